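test_that("summaries reproduce hand-computed mean and SD", {
  tab <- tibble::tibble(
    subject = "s", group = "control", roi = "NAWM", segment = 1L,
    block_row = 0:2, block_col = 0L, flair_mean = 100,
    metric_name = "LFB", metric_value = c(10, 20, 30),
    tissue_fraction = 1, included = TRUE)
  sm <- summarize_blocks(tab)
  all_row <- sm[sm$segment == "all", ]
  expect_equal(all_row$mean, 20)
  expect_equal(all_row$sd, 10) # sqrt((100 + 0 + 100)/2)
  expect_equal(all_row$n_blocks, 3L)
  one <- summarize_blocks(tab[1, ])
  expect_true(all(one$sd == 0))
  expect_true(all(one$single_block))
})

test_that("one-way ANOVA matches the textbook sums-of-squares oracle", {
  d <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  g = rep(c("A", "B", "C"), each = 3))
  fit <- anova_glm(d, "y", "g")
  row <- tidy(fit)
  expect_equal(row$statistic, 3.0, tolerance = 1e-9)
  expect_equal(c(row$df, row$df_residual), c(2, 6))
  # independent oracle: direct SSB/SSW computation
  gm <- mean(d$y)
  ssb <- sum(tapply(d$y, d$g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(d$y, d$g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(row$statistic, f_oracle, tolerance = 1e-9)
  expect_equal(row$p_raw, stats::pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-9)
  # constant response: F = 0, p = 1
  d0 <- data.frame(y = rep(2, 9), g = d$g)
  expect_equal(tidy(anova_glm(d0, "y", "g"))$statistic, 0)
  expect_equal(tidy(anova_glm(d0, "y", "g"))$p_raw, 1)
})

test_that("an uninformative covariate leaves the group F essentially unchanged", {
  set.seed(19)
  n <- 600
  d <- data.frame(y = rnorm(n) + rep(c(0, 0.4), each = n / 2),
                  g = rep(c("A", "B"), each = n / 2),
                  cov = rnorm(n))
  f_un <- tidy(anova_glm(d, "y", "g"))$statistic
  f_ad <- dplyr::filter(tidy(anova_glm(d, "y", "g", "cov")),
                        effect == "g")$statistic
  expect_lt(abs(f_un - f_ad) / f_un, 0.05)
  # rank deficiency is reported, not silently dropped
  d$g2 <- d$g
  expect_error(anova_glm(d, "y", c("g", "g2")), "rank deficient")
  expect_error(anova_glm(d, "y", "y2"), "levels")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1)
  p <- runif(20)
  expect_true(all(bonferroni(p, 4) >= p))
  expect_true(all(bonferroni(p, 4) <= 1))
})

test_that("pairwise segment contrasts report direction and adjusted p", {
  set.seed(7)
  tab <- tibble::tibble(
    subject = "s", group = "control", roi = "WMH",
    segment = rep(1:3, each = 30), block_row = 0:89, block_col = 0L,
    flair_mean = rep(c(100, 120, 140), each = 30),
    metric_name = "LFB",
    metric_value = rep(c(60, 45, 30), each = 30) + rnorm(90, 0, 5),
    tissue_fraction = 1, included = TRUE)
  ct <- pairwise_segments(tab, "LFB", "WMH")
  expect_equal(ct$comparison, c("2 vs 1", "3 vs 1", "3 vs 2"))
  expect_true(all(ct$difference < 0))
  expect_equal(ct$p_bonferroni, pmin(1, 3 * ct$p_raw))
  expect_true(all(ct$significant))
  expect_error(pairwise_segments(tab[tab$segment != 2, ], "LFB", "WMH"),
               "< 2 blocks")
})

test_that("pearson matches the closed-form product-moment oracle", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2))$r, -1)
  p4 <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(p4$r, 0.8, tolerance = 1e-12)
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    y <- rnorm(length(x))
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    got <- pearson(x, y)
    expect_equal(got$r, r_oracle, tolerance = 1e-12)
    t_or <- r_oracle * sqrt((length(x) - 2) / (1 - r_oracle^2))
    expect_equal(got$p_value,
                 2 * stats::pt(abs(t_or), length(x) - 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson(1:2, 1:2), "3 complete")
})

test_that("percent differences follow the reporting convention", {
  expect_equal(percent_difference(44.8, 30.5), -31.9, tolerance = 0.02)
  expect_equal(percent_difference(10, 25), 150)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(0, 3), "zero")
})
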