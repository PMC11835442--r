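#' 1-D k-means with k-means++ restarts
#'
#' Clusters scalar FLAIR intensities by Lloyd's algorithm started from
#' k-means++ seedings; the best of `n_restarts` runs by within-cluster sum of
#' squares is kept. Because optimal 1-D clusters are contiguous in sorted
#' order, small instances (`n <= 512`) are additionally checked against the
#' exact contiguous-partition dynamic program and larger ones are polished by
#' a split-boundary descent, so the returned solution is globally optimal on
#' small inputs and at least a strong local optimum on image-sized ones.
#' Centroids are returned sorted ascending, so that segment 1 is always the
#' lowest-intensity cluster and segment `k` the highest.
#'
#' @param values Numeric vector to cluster (at least `k` distinct values).
#' @param k Number of clusters (default 3, the white matter segment count).
#' @param n_restarts Number of independent k-means++ seedings (default 10).
#' @param seed Integer seed making the restarts reproducible.
#' @return Numeric vector of `k` ascending centroids with attribute `wcss`.
#' @export
fit_kmeans_1d <- function(values, k = 3, n_restarts = 10, seed = 1) {
  values <- as.numeric(values)
  if (anyNA(values)) values <- values[!is.na(values)]
  ux <- unique(values)
  if (k < 1) abort("k must be >= 1")
  if (length(ux) < k) {
    abort(sprintf("degenerate mask: %d distinct values < k = %d", length(ux), k))
  }
  if (k == 1) {
    cen <- mean(values)
    return(structure(cen, wcss = sum((values - cen)^2)))
  }
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_restarts)) {
      init <- kmeanspp_init(values, k)
      # Lloyd can empty a cluster from an unlucky seeding; drop that restart
      fit <- tryCatch(
        stats::kmeans(values, centers = matrix(init, ncol = 1),
                      iter.max = 100, algorithm = "Lloyd"),
        error = function(e) NULL
      )
      if (!is.null(fit) &&
          (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) abort("all k-means restarts failed")
  xs <- sort(values)
  ref <- if (length(xs) <= 512) {
    kmeans_1d_dp(xs, k)
  } else {
    kmeans_1d_refine(xs, k, sort(as.numeric(best$centers)))
  }
  # keep whichever of Lloyd / polish is better (they agree almost always)
  if (best$tot.withinss < ref$wcss - 1e-12) {
    ref <- list(centroids = sort(as.numeric(best$centers)),
                wcss = best$tot.withinss)
  }
  structure(ref$centroids, wcss = ref$wcss)
}

# exact 1-D k-means on sorted data by dynamic programming over contiguous
# partitions; O(k n^2) with O(1) segment costs from prefix sums
kmeans_1d_dp <- function(xs, k) {
  n <- length(xs)
  s1 <- c(0, cumsum(xs))
  s2 <- c(0, cumsum(xs^2))
  seg_cost <- function(i, j) {
    s <- s1[j + 1] - s1[i]
    s2[j + 1] - s2[i] - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in 1:n) D[1, j] <- seg_cost(1, j)
  if (k > 1) {
    for (g in 2:k) {
      for (j in g:n) {
        cand <- vapply(g:j, function(i) D[g - 1, i - 1] + seg_cost(i, j),
                       numeric(1))
        best_i <- which.min(cand)
        D[g, j] <- cand[best_i]
        back[g, j] <- (g:j)[best_i]
      }
    }
  }
  # reconstruct segment start indices
  starts <- integer(k)
  j <- n
  for (g in k:1) {
    starts[g] <- if (g == 1) 1L else back[g, j]
    j <- starts[g] - 1L
  }
  ends <- c(starts[-1] - 1L, n)
  cen <- vapply(seq_len(k), function(g) mean(xs[starts[g]:ends[g]]),
                numeric(1))
  list(centroids = sort(cen), wcss = D[k, n])
}

# split-boundary descent on sorted 1-D data: clusters are the segments
# between k-1 split indices; each boundary is moved one element at a time
# while the within-cluster sum of squares decreases
kmeans_1d_refine <- function(xs, k, centroids) {
  n <- length(xs)
  s1 <- c(0, cumsum(xs))
  s2 <- c(0, cumsum(xs^2))
  seg_cost <- function(i, j) {
    s <- s1[j + 1] - s1[i]
    s2[j + 1] - s2[i] - s^2 / (j - i + 1)
  }
  # initial contiguous partition from nearest-centroid boundaries
  cuts <- findInterval((centroids[-k] + centroids[-1]) / 2, xs)
  # force strictly increasing cuts inside 1..n-1 (non-empty segments)
  for (b in seq_len(k - 1)) {
    lo_b <- if (b == 1) 1 else cuts[b - 1] + 1
    cuts[b] <- min(max(cuts[b], lo_b), n - (k - b))
  }
  total <- function(cuts) {
    lo <- c(1, cuts + 1)
    hi <- c(cuts, n)
    sum(vapply(seq_len(k), function(g) seg_cost(lo[g], hi[g]), numeric(1)))
  }
  w <- total(cuts)
  repeat {
    improved <- FALSE
    for (b in seq_len(k - 1)) {
      lo <- if (b == 1) 1 else cuts[b - 1] + 1
      hi <- if (b == k - 1) n - 1 else cuts[b + 1] - 1
      for (cand in c(cuts[b] - 1, cuts[b] + 1)) {
        if (cand < lo || cand > hi) next
        trial <- cuts
        trial[b] <- cand
        wt <- total(trial)
        if (wt < w - 1e-12) {
          cuts <- trial
          w <- wt
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  lo <- c(1, cuts + 1)
  hi <- c(cuts, n)
  cen <- vapply(seq_len(k), function(g) mean(xs[lo[g]:hi[g]]), numeric(1))
  list(centroids = sort(cen), wcss = w)
}

# k-means++ seeding on scalar data: first centre uniform, later centres with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_init <- function(values, k) {
  ux <- unique(values)
  centres <- ux[sample.int(length(ux), 1)]
  while (length(centres) < k) {
    d2 <- vapply(values, function(v) min((v - centres)^2), numeric(1))
    # restrict to unseen values to guarantee distinct centres
    cand <- !(values %in% centres)
    p <- d2 * cand
    if (sum(p) == 0) {
      centres <- c(centres, setdiff(ux, centres)[1])
    } else {
      centres <- c(centres, values[sample.int(length(values), 1, prob = p)])
    }
  }
  centres
}

#' Exact 1-D k-means oracle
#'
#' Exhaustive optimum for tiny instances: optimal 1-D k-means clusters are
#' contiguous in sorted order, so all contiguous partitions of the sorted
#' values are enumerated and the minimum within-cluster sum of squares is
#' returned. Intended as an independent reference for [fit_kmeans_1d()].
#'
#' @param values Numeric vector, `length(values) <= 12`.
#' @param k Number of clusters.
#' @return List with `wcss`, ascending `centroids`, and `assignment` (cluster
#'   index per element of the sorted values).
#' @export
kmeans_oracle <- function(values, k) {
  n <- length(values)
  if (n > 12) abort("oracle restricted to n <= 12")
  if (k > n) abort("k exceeds the number of values")
  x <- sort(as.numeric(values))
  wcss_seg <- function(i, j) {
    s <- x[i:j]
    sum((s - mean(s))^2)
  }
  if (k == 1) {
    return(list(wcss = wcss_seg(1, n), centroids = mean(x),
                assignment = rep(1L, n)))
  }
  best <- list(wcss = Inf)
  splits <- utils::combn(n - 1, k - 1)
  for (s in seq_len(ncol(splits))) {
    cut <- c(0, splits[, s], n)
    w <- 0
    cen <- numeric(k)
    asg <- integer(n)
    for (g in seq_len(k)) {
      i <- cut[g] + 1; j <- cut[g + 1]
      w <- w + wcss_seg(i, j)
      cen[g] <- mean(x[i:j])
      asg[i:j] <- g
    }
    if (w < best$wcss) best <- list(wcss = w, centroids = cen, assignment = asg)
  }
  best
}

#' Assign ordered intensity segments within a region of interest
#'
#' Labels every in-mask FLAIR pixel by its nearest centroid; the label is the
#' centroid's ascending rank, so segment 1 holds the lowest FLAIR signal and
#' segment 3 the highest. A pixel exactly midway between two centroids takes
#' the lower segment (deterministic, conservative toward "less abnormal").
#'
#' @param flair An [mri_slice()] or numeric matrix of FLAIR signal.
#' @param roi_mask Logical matrix selecting the ROI (WMH or NAWM).
#' @param centroids Ascending centroid vector from [fit_kmeans_1d()].
#' @return Integer matrix: 0 outside the ROI, segment index 1..k inside.
#' @export
assign_segments <- function(flair, roi_mask, centroids) {
  vals <- if (inherits(flair, "mri_slice")) flair$values else flair
  if (!any(roi_mask)) abort("empty ROI mask")
  if (is.unsorted(centroids)) abort("centroids must be ascending")
  x <- vals[roi_mask]
  d <- abs(outer(x, as.numeric(centroids), "-"))
  # ties -> lower segment: max.col with ties.method "first" on negated distance
  lab <- max.col(-d, ties.method = "first")
  out <- matrix(0L, nrow(vals), ncol(vals))
  out[roi_mask] <- lab
  out
}

#' Grade WMH and NAWM into intensity segments
#'
#' Runs [fit_kmeans_1d()] separately within the WMH mask and the NAWM mask of
#' a segmentation map and labels each ROI's pixels into ordered segments
#' 1..k with [assign_segments()].
#'
#' @param flair FLAIR image on the same grid as `seg` ([mri_slice()] or
#'   matrix).
#' @param seg Label matrix with codes 0 background, 1 GM, 2 NAWM, 3 WMH.
#' @param k Number of segments per ROI (default 3).
#' @param n_restarts,seed Passed to [fit_kmeans_1d()].
#' @return Object of class `graded_map`: list with integer segment matrices
#'   `wmh` and `nawm` (0 outside the ROI) and a `centroids` list.
#' @export
grade_rois <- function(flair, seg, k = 3, n_restarts = 10, seed = 1) {
  vals <- if (inherits(flair, "mri_slice")) flair$values else flair
  stopifnot(all(dim(vals) == dim(seg)))
  out <- list(centroids = list())
  for (roi in c("NAWM", "WMH")) {
    code <- if (roi == "WMH") 3L else 2L
    mask <- !is.na(seg) & seg == code & !is.na(vals)
    if (!any(mask)) abort(sprintf("ROI %s is empty", roi))
    cen <- fit_kmeans_1d(vals[mask], k = k, n_restarts = n_restarts,
                         seed = derive_seed(seed, roi))
    out[[tolower(roi)]] <- assign_segments(vals, mask, cen)
    out$centroids[[roi]] <- as.numeric(cen)
  }
  structure(out, class = "graded_map")
}
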