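test_that("Kruskal-Wallis H matches hand computation, rank invariance and degeneracy", {
  # {1,2,3} vs {4,5,6}: rank sums 6 and 15, H = 12/(6*7) * (12 + 75) - 3*7
  kw <- kw_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-10)
  expect_equal(kw$p_value, 0.0495, tolerance = 1e-2)

  kw_same <- kw_test(rep(c(2, 2, 2), 2), rep(c("a", "b"), each = 3))
  expect_equal(kw_same$H, 0)
  expect_equal(kw_same$p_value, 1)

  set.seed(41)
  x <- rnorm(12); g <- rep(c("a", "b"), 6)
  o <- sample(12)
  expect_equal(kw_test(x, g)$H, kw_test(x[o], g[o])$H, tolerance = 1e-12)

  # monotone transforms leave ranks (hence H) unchanged
  expect_equal(kw_test(exp(x), g)$H, kw_test(x, g)$H, tolerance = 1e-12)
})

test_that("the chi-square p approximates an independent permutation oracle", {
  set.seed(42)
  x <- c(0.3, 1.2, 2.4, 0.8, 3.1, 2.0, 4.2, 3.3, 1.9, 2.8)
  g <- rep(c("a", "b"), each = 5)
  h_obs <- kw_test(x, g)$H
  perm <- replicate(20000, {
    gp <- sample(g)
    kruskal.test(x, factor(gp))$statistic
  })
  p_perm <- mean(perm >= h_obs - 1e-12)
  expect_lt(abs(kw_test(x, g)$p_value - p_perm), 0.05)
})

test_that("group comparison tables carry per-group summaries and flags", {
  set.seed(43)
  params <- tibble::tibble(
    group = rep(c("control", "case"), each = 10),
    acrophase_deg = c(rnorm(10, 232, 8), rnorm(10, 253, 8)),
    mesor = rnorm(20, 216, 20)
  )
  cmp <- compare_groups(params, c("acrophase_deg", "mesor"))
  expect_equal(cmp$parameter, c("acrophase_deg", "mesor"))
  expect_true(cmp$significant[1])
  expect_equal(cmp$mean_control[1], mean(params$acrophase_deg[params$group == "control"]))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$H >= 0))
})

test_that("24h profile flags differences on the limbs for shifted groups, nothing much for identical", {
  # narrow between-subject mesor spread isolates the injected phase shift
  # (a wide spread only adds heavy correlation between the per-minute tests)
  coh <- generate_cohort(
    cohort_spec(n_subjects = 8, acrophase_mean = 232, mesor_sd = 15,
                noise_scale = 150, seed = 44),
    cohort_spec(n_subjects = 8, acrophase_mean = 253, mesor_sd = 15,
                noise_scale = 150, seed = 45)
  )
  prof <- mean_24h_profile(coh)
  expect_equal(nrow(prof$minutes), 1440)
  sig <- prof$minutes$minute[prof$minutes$significant]
  expect_gt(length(sig), 40)
  # difference of two shifted cosines peaks a quarter cycle off the mid
  # acrophase: ~09:40 and ~21:40 for acrophases at 232 and 253 degrees
  mid_peak_min <- mean(c(232, 253)) / 360 * 1440
  limbs <- c((mid_peak_min - 360) %% 1440, (mid_peak_min + 360) %% 1440)
  near_limb <- vapply(sig, function(m) {
    dd <- abs(m - limbs)
    min(pmin(dd, 1440 - dd)) <= 240
  }, logical(1))
  expect_gt(mean(near_limb), 0.5)

  same <- generate_cohort(
    cohort_spec(n_subjects = 8, mesor_sd = 15, noise_scale = 150, seed = 46),
    cohort_spec(n_subjects = 8, mesor_sd = 15, noise_scale = 150, seed = 47)
  )
  prof0 <- mean_24h_profile(same)
  expect_lt(mean(prof0$minutes$significant), 0.15)

  solo <- generate_cohort(cohort_spec(n_subjects = 1, n_days = 1, seed = 1),
                          cohort_spec(n_subjects = 1, n_days = 1, seed = 2))
  expect_error(mean_24h_profile(solo), "2 subjects")
})

test_that("cosinor and SSA describe a clean cosine identically, and anti-phase flips the sign", {
  s <- generate_subject(noisefree_spec(seed = 48), 0)
  fit <- fit_cosinor(s)
  rec <- circadian_reconstruction(ssa_decompose(s))
  agr <- cosinor_ssa_agreement(fit, rec)
  expect_equal(agr$pearson_r, 1, tolerance = 1e-4)
  expect_equal(agr$spearman_rho, 1, tolerance = 1e-3)

  t <- 0:999
  a <- cos(2 * pi * t / 200)
  expect_equal(cosinor_ssa_agreement(a, -a)$pearson_r, -1, tolerance = 1e-12)
  expect_warning(res <- cosinor_ssa_agreement(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(res$pearson_r))
})

test_that("realistic subjects give the expected cosinor-SSA agreement scale", {
  rs <- vapply(1:4, function(i) {
    s <- generate_subject(cohort_spec(n_subjects = 1, seed = 50 + i), 0)
    rec <- circadian_reconstruction(ssa_decompose(s))
    cosinor_ssa_agreement(fit_cosinor(s), rec)$pearson_r
  }, numeric(1))
  expect_gt(mean(rs), 0.6)
  expect_lt(mean(rs), 0.98)
})
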