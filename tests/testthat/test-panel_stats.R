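toy_panel <- function(counts, sizes = NULL) {
  n <- nrow(counts)
  if (is.null(sizes)) sizes <- seq(3e6, 3e6 + (n - 1) * 1e6, by = 1e6)
  panel_matrix(sprintf("g%02d", seq_len(n)), sizes, counts)
}

test_that("z-scores use the population sd and handle degenerate panels", {
  p <- toy_panel(data.frame(tcs = c(10, 20, 30)))
  z <- zscore_table(p)
  expect_equal(unname(z[, "tcs"]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(z[, "tcs"]), 0)
  expect_equal(sqrt(mean(z[, "tcs"]^2)), 1)

  # constant category: all zeros with a warning
  pc <- toy_panel(data.frame(tcs = c(5, 5, 5)))
  expect_warning(zc <- zscore_table(pc), "zero variance")
  expect_equal(unname(zc[, "tcs"]), c(0, 0, 0))

  # translation invariance
  p2 <- toy_panel(data.frame(tcs = c(10, 20, 30) + 7))
  expect_equal(zscore_table(p2), zscore_table(p))

  expect_error(zscore_table(toy_panel(data.frame(tcs = 5))), "at least 2")
})

test_that("combined score averages the four category z-scores", {
  counts <- data.frame(tcs = c(10, 20, 30), tf = c(100, 200, 300),
                       transport = c(1, 2, 3), defense = c(7, 8, 9))
  p <- toy_panel(counts)
  s <- combined_scores(p)
  # every category is an affine image of the same pattern -> equal z-scores
  expect_equal(unname(s), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # genome at the panel mean scores 0
  expect_equal(unname(s[2]), 0)
  expect_error(combined_scores(p, categories = c("tcs", "nope")),
               "missing from panel")
})

test_that("a genome 2.2793 sd above the TF mean gets that z-score", {
  # 10-genome panel engineered to have TF mean 158 and population sd 111
  # with one genome at 411: its z-score must equal (411 - 158) / 111
  v <- c(-4, -3, -2, -1, 0, 1, 2, 3, 4)
  others_mean <- (10 * 158 - 411) / 9
  ss_others <- 10 * 111^2 - (411 - 158)^2
  a <- sqrt((ss_others - 9 * (others_mean - 158)^2) / sum(v^2))
  tf <- c(others_mean + a * v, 411)
  p <- toy_panel(data.frame(tf = tf))
  expect_equal(mean(tf), 158, tolerance = 1e-9)
  expect_equal(sqrt(mean((tf - 158)^2)), 111, tolerance = 1e-9)
  z <- zscore_table(p)
  expect_equal(unname(z[10, "tf"]), (411 - 158) / 111, tolerance = 1e-9)
  expect_equal(unname(z[10, "tf"]), 2.2793, tolerance = 1e-4)
})

test_that("combined score is invariant to per-category affine rescaling", {
  set.seed(5)
  counts <- data.frame(tcs = rpois(20, 50), tf = rpois(20, 150),
                       transport = rpois(20, 400), defense = rpois(20, 30))
  p <- toy_panel(counts)
  s1 <- combined_scores(p)
  rescaled <- data.frame(tcs = 3 * counts$tcs + 10, tf = 0.5 * counts$tf,
                         transport = counts$transport + 100,
                         defense = 10 * counts$defense)
  s2 <- combined_scores(toy_panel(rescaled))
  expect_equal(s1, s2)
})

test_that("regression recovers a perfect line and a noisy generator slope", {
  sizes <- seq(2e6, 8e6, length.out = 7)
  p <- panel_matrix(sprintf("g%d", 1:7), sizes,
                    data.frame(tcs = 10 * sizes / 1e6))
  fit <- fit_count_size_regression(p, "tcs")
  expect_equal(fit$slope_per_mbp, 10, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(fit$r, 1)

  gp <- gen_panel(n = 200, slopes = c(tcs = 12), noise_sd = c(tcs = 5),
                  outlier = FALSE, seed = 31)
  fit2 <- fit_count_size_regression(gp$panel, "tcs")
  expect_lt(abs(fit2$slope_per_mbp - 12), 1)

  # counts independent of size: |r| small
  set.seed(8)
  p3 <- panel_matrix(sprintf("g%d", 1:200), runif(200, 2e6, 1e7),
                     data.frame(tcs = rpois(200, 60)))
  fit3 <- fit_count_size_regression(p3, "tcs")
  expect_lt(abs(fit3$r), 0.2)
  ci <- confint(fit3$fit)["size_mbp", ]
  expect_true(ci[1] < 0 && ci[2] > 0)

  expect_error(fit_count_size_regression(
    panel_matrix(c("a", "b", "c"), c(5e6, 5e6, 5e6),
                 data.frame(tcs = 1:3)), "tcs"), "degenerate")
})

test_that("percentile ranks use strictly-smaller counting with shared ties", {
  vals <- stats::setNames(1:500, sprintf("g%03d", 1:500))
  rf <- rank_and_flag(vals, top_fraction = 0.01)
  expect_equal(rf["g500", "rank"], 499 / 500)
  expect_true(rf["g500", "flagged"])
  expect_equal(rf["g001", "rank"], 0)
  expect_false(rf["g001", "flagged"])
  expect_equal(sum(rf$flagged), 5L)   # upper 1% of 500

  tied <- rank_and_flag(rep(3, 10), top_fraction = 0.05)
  expect_true(all(tied$rank == 0))
  expect_false(any(tied$flagged))

  expect_error(rank_and_flag(numeric(0)), "empty")
})

test_that("COG-profile clustering separates planted profile families", {
  set.seed(12)
  n_cogs <- 60
  fam_a <- c(rep(40, 30), rep(1, 30))
  fam_b <- c(rep(1, 30), rep(40, 30))
  profiles <- rbind(
    t(sapply(1:6, function(i) rpois(n_cogs, fam_a))),
    t(sapply(1:6, function(i) rpois(n_cogs, fam_b))))
  rownames(profiles) <- c(sprintf("a%d", 1:6), sprintf("b%d", 1:6))
  cl <- cog_profile_cluster(profiles)
  expect_equal(cl$correlation, t(cl$correlation))
  expect_equal(unname(diag(cl$correlation)), rep(1, 12))
  fams <- substr(cl$order, 1, 1)
  expect_equal(length(rle(fams)$lengths), 2L)   # contiguous blocks

  # identical profiles correlate at 1
  two <- rbind(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  expect_equal(cog_profile_cluster(two)$correlation["x", "y"], 1)

  # zero-variance profile: warning, correlations 0
  flat <- rbind(x = c(1, 2, 3, 4), y = c(2, 2, 2, 2), z = c(4, 3, 2, 1))
  expect_warning(czero <- cog_profile_cluster(flat), "zero-variance")
  expect_equal(unname(czero$correlation["y", "x"]), 0)
})
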