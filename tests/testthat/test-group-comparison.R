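make_summaries <- function(values, groups) {
  data.frame(recording_id = paste0("r", seq_along(values)),
             morph = groups, mean_interval_left = values,
             stringsAsFactors = FALSE)
}

test_that("identical groups give a no-signal comparison", {
  s <- make_summaries(rep(2.5, 9), rep(c("a", "b", "c"), each = 3))
  gc <- compare_groups(s, "mean_interval_left")
  expect_equal(gc$kruskal$H, 0)
  expect_equal(gc$kruskal$p, 1)
  expect_true(all(gc$pairwise$p_bonferroni == 1))
})

test_that("complete separation yields W = 0 for the low-shifted first group", {
  s <- make_summaries(c(1, 2, 3, 10, 20, 30), rep(c("a", "b"), each = 3))
  gc <- compare_groups(s, "mean_interval_left")
  expect_equal(gc$pairwise$W, 0)
  # exact two-sided p for complete separation at 3 vs 3: 2 / choose(6, 3)
  expect_equal(gc$pairwise$p_raw, 2 / choose(6, 3))
})

test_that("pairwise rank-sum p-values match exhaustive enumeration", {
  cases <- list(
    list(x = c(1.2, 3.4, 2.2), y = c(5.1, 0.4, 9.9)),
    list(x = c(1, 2, 3), y = c(10, 20, 30)),
    list(x = c(0.3, 7.2, 2.5, 4.4), y = c(1.1, 6.6)),
    list(x = c(2, 4, 6, 8, 10), y = c(1, 3, 5, 7, 9, 11))
  )
  for (cs in cases) {
    s <- make_summaries(c(cs$x, cs$y),
                        rep(c("a", "b"), c(length(cs$x), length(cs$y))))
    gc <- compare_groups(s, "mean_interval_left")
    oracle <- ranksum_enum_oracle(cs$x, cs$y)
    expect_equal(gc$pairwise$W, oracle$W)
    expect_equal(gc$pairwise$p_raw, oracle$p, tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment multiplies by the pairwise family size", {
  set.seed(5)
  s <- make_summaries(rnorm(12), rep(c("a", "b", "c"), each = 4))
  gc <- compare_groups(s, "mean_interval_left")
  expect_identical(nrow(gc$pairwise), 3L) # 3 groups -> 3 pairs
  expect_equal(gc$pairwise$p_bonferroni,
               pmin(1, gc$pairwise$p_raw * 3))
  expect_true(all(gc$pairwise$p_bonferroni >= gc$pairwise$p_raw))
  expect_true(all(gc$pairwise$p_bonferroni <= 1))
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(9)
  v <- rlnorm(10)
  g <- rep(c("a", "b"), each = 5)
  gc1 <- compare_groups(make_summaries(v, g), "mean_interval_left")
  gc2 <- compare_groups(make_summaries(log(v), g), "mean_interval_left")
  gc3 <- compare_groups(make_summaries(v^3, g), "mean_interval_left")
  expect_equal(gc2$pairwise$p_raw, gc1$pairwise$p_raw)
  expect_equal(gc3$pairwise$W, gc1$pairwise$W)
  expect_equal(gc2$kruskal$H, gc1$kruskal$H)
})

test_that("group comparison validates its inputs", {
  s <- make_summaries(c(1, 2, NA), c("a", "a", "b"))
  expect_error(compare_groups(s, "mean_interval_left"), "group 'b'")
  expect_error(compare_groups(make_summaries(1:3, rep("a", 3)),
                              "mean_interval_left"), "2 groups")
  expect_error(compare_groups(s, "nope"), "not a column")
})

test_that("temperature correlation recovers monotone relations and the closed form", {
  s <- data.frame(recording_id = paste0("r", 1:4),
                  water_temp_c = c(17, 19, 21, 23),
                  mean_interval_left = c(3.1, 2.4, 2.0, 1.2))
  dec <- temperature_correlation(s)
  expect_equal(dec$rho, -1)
  s$mean_interval_left <- rev(s$mean_interval_left)
  expect_equal(temperature_correlation(s)$rho, 1)
  s$mean_interval_left <- c(2.0, 3.1, 1.2, 2.4)
  tc <- temperature_correlation(s)
  expect_equal(tc$rho,
               spearman_closed_form(s$water_temp_c, s$mean_interval_left))
  expect_error(temperature_correlation(s[1:2, ]), "at least 3")
})

test_that("bootstrap resampling is sized, seeded and unbiased", {
  expect_error(bootstrap_movements(numeric(0), seed = 1), "non-empty")
  expect_identical(bootstrap_movements(c(7), 1000, seed = 1), rep(7, 1000))
  b1 <- bootstrap_movements(c(1, 2, 3), seed = 42)
  b2 <- bootstrap_movements(c(1, 2, 3), seed = 42)
  expect_identical(b1, b2)
  expect_length(b1, 1000L)
  big <- bootstrap_movements(c(1, 2, 3), n_boot = 40000, seed = 3)
  se <- sd(c(1, 2, 3)) / sqrt(40000)
  expect_lt(abs(mean(big) - 2), 3 * se)
  # the bootstrap leaves the caller's RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(bootstrap_movements(1:5, seed = 99)); after <- runif(1)
  expect_identical(before, after)
})

test_that("mixed model recovers simulated group differences", {
  set.seed(21)
  # two groups of recordings, true means 0.2 s and 3.2 s, small
  # between-recording variance
  mk <- function(id, mu, g) {
    data.frame(recording_id = id, group = g,
               value = rnorm(200, mu + rnorm(1, 0, 0.05), 0.1))
  }
  dat <- rbind(
    do.call(rbind, lapply(1:6, function(i) mk(paste0("a", i), 0.2, "fast"))),
    do.call(rbind, lapply(1:6, function(i) mk(paste0("b", i), 3.2, "slow")))
  )
  fit <- fit_interval_mixed_model(dat)
  diff_est <- fit$group_means[["slow"]] - fit$group_means[["fast"]]
  se <- fit$coefficients["groupslow", "Std. Error"]
  expect_lt(abs(diff_est - 3), 1.96 * se + 0.15)
  expect_true(all(is.finite(fit$coefficients[, "df"])))
  expect_gte(fit$ranef_variance, 0)
})

test_that("identical bootstrap sets across groups give a null effect", {
  vals <- rep(c(1, 2, 3, 4), 25)
  dat <- rbind(
    data.frame(recording_id = "a1", group = "g1", value = vals),
    data.frame(recording_id = "a2", group = "g1", value = vals),
    data.frame(recording_id = "b1", group = "g2", value = vals),
    data.frame(recording_id = "b2", group = "g2", value = vals)
  )
  fit <- fit_interval_mixed_model(dat)
  expect_equal(unname(fit$coefficients["groupg2", "Estimate"]), 0,
               tolerance = 1e-8)
  expect_true(fit$singular) # zero between-recording variance is flagged
})

test_that("random intercepts keep inference driven by between-recording variation", {
  recs <- simulate_study(c(congener = 3, darter_morph = 3, leech_morph = 3),
                         seed = 8)
  b_small <- bootstrap_study(recs, n_boot = 100, seed = 2)
  b_large <- bootstrap_study(recs, n_boot = 1000, seed = 2)
  f_small <- fit_interval_mixed_model(b_small)
  f_large <- fit_interval_mixed_model(b_large)
  se_s <- f_small$coefficients[-1L, "Std. Error"]
  se_l <- f_large$coefficients[-1L, "Std. Error"]
  expect_true(all(abs(se_l - se_s) / se_s < 0.10))
})
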