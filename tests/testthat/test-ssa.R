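test_that("the trajectory matrix is Hankel with element [i, j] = x[i + j - 1]", {
  X <- ssa_embed(c(1, 2, 3, 4, 5), 2)
  expect_equal(dim(X), c(4, 2))
  expect_equal(X, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  x <- rnorm(20)
  L <- 7
  X <- ssa_embed(x, L)
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    expect_identical(X[i, j], x[i + j - 1])
  }
  expect_equal(qr(ssa_embed(rep(3, 10), 4))$rank, 1)
  expect_error(ssa_embed(x, 11), "N/2")
})

test_that("diagonal averaging inverts the embedding and is linear", {
  expect_equal(diagonal_average(rbind(c(1, 2), c(3, 4))), c(1, 2.5, 4))
  x <- rnorm(15)
  expect_equal(diagonal_average(ssa_embed(x, 5)), x)
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(12), 4, 3)
  expect_equal(diagonal_average(A + B),
               diagonal_average(A) + diagonal_average(B), tolerance = 1e-12)
})

test_that("a pure sine concentrates in a nearly degenerate pair; white noise does not", {
  x <- sin(2 * pi * (0:2879) / 288)
  d <- ssa_decompose(x, L = 288)
  frac <- d$lambda / d$lambda_tot
  expect_gte(frac[1] + frac[2], 0.999)
  expect_lt(abs(d$lambda[1] - d$lambda[2]) / d$lambda[1], 0.02)

  set.seed(8)
  dn <- ssa_decompose(rnorm(400), L = 200)
  frac_n <- dn$lambda / dn$lambda_tot
  expect_lt(max(frac_n) / median(frac_n), 20)     # flat-ish scree, no step
  # versus the sharp step below the pair when the sine is full rank
  xn <- sin(2 * pi * (0:2879) / 288) + rnorm(2880, 0, 0.05)
  fs <- ssa_scree(ssa_decompose(xn, L = 288))$lambda_frac
  expect_gt(fs[2] / fs[3], 50)
})

test_that("constant series decompose to a single constant component", {
  d <- ssa_decompose(rep(4, 40), L = 10)
  expect_equal(d$r, 1)
  g <- ssa_components(d, 1)[, 1]
  expect_equal(sd(g), 0, tolerance = 1e-12)
  expect_equal(ssa_reconstruct(d, 1), rep(4, 40), tolerance = 1e-10)
})

test_that("full-rank reconstruction is exact and energy is conserved", {
  set.seed(9)
  for (case in 1:3) {
    n <- sample(40:200, 1)
    x <- switch(case,
                rnorm(n),
                cumsum(rnorm(n)),
                10 + 5 * sin(2 * pi * seq_len(n) / 17) + rnorm(n, 0, 0.3))
    L <- sample(2:(n %/% 2), 1)
    d <- ssa_decompose(x, L = L)
    expect_lt(max(abs(ssa_reconstruct(d) - x)) / max(abs(x)), 1e-8)
    expect_equal(sum(d$lambda), sum(ssa_embed(x, L)^2), tolerance = 1e-8)
  }
})

test_that("decomposition matches an independent dense SVD oracle on small series", {
  set.seed(10)
  for (rep in 1:3) {
    n <- sample(20:50, 1)
    L <- sample(3:(n %/% 2), 1)
    x <- rnorm(n)
    d <- ssa_decompose(x, L = L)
    o <- ssa_oracle(x, L)
    expect_equal(d$sigma, o$d, tolerance = 1e-8)
    # physical components sigma_k * g_k are sign-unambiguous (u and v flip
    # together), so they must match the oracle elementwise
    got <- ssa_components(d) %*% diag(d$sigma)
    expect_lt(max(abs(got - o$comps)), 1e-8)
  }
})

test_that("scree fractions are ordered, positive and sum to one at full rank", {
  set.seed(11)
  d <- ssa_decompose(abs(rnorm(120, 10, 3)), L = 30)
  s <- ssa_scree(d)
  expect_true(all(diff(s$lambda_frac) <= 1e-12))
  expect_true(all(s$lambda_frac > 0))
  expect_equal(sum(s$lambda_frac), 1, tolerance = 1e-10)
})

test_that("as L grows toward N/2 a sinusoid's pair share approaches one", {
  x <- sin(2 * pi * (0:1151) / 96)
  share <- vapply(c(96, 288, 576), function(L) {
    d <- ssa_decompose(x, L = L)
    sum(d$lambda[1:2]) / d$lambda_tot
  }, numeric(1))
  expect_true(all(diff(share) >= -1e-12))
  expect_gte(share[3], 0.999)
})

test_that("w-correlation has unit diagonal, the documented weights, and separates trend from pair", {
  expect_equal(chronossa:::diag_weights(4L, 2L), c(1, 2, 2, 2, 1))
  x <- 5 + sin(2 * pi * (0:959) / 96)
  d <- ssa_decompose(x, L = 192)
  W <- ssa_wcor(d, 1:3)
  expect_equal(diag(W), rep(1, 3))
  expect_equal(W, t(W), tolerance = 1e-12)
  expect_lt(max(abs(W[1, 2:3])), 0.1)
})

test_that("component periods: sinusoid recovered within a minute, ramps labelled trend", {
  expect_equal(estimate_component_period(sin(2 * pi * (0:2879) / 288)), 288,
               tolerance = 1 / 288)
  expect_equal(estimate_component_period(seq_len(500)), Inf)
  expect_equal(estimate_component_period(rep(2, 100)), Inf)
})

test_that("a generated subject yields a circadian pair near 1440 min, auto-detected", {
  s <- generate_subject(cohort_spec(n_subjects = 1, seed = 13), 0)
  d <- ssa_decompose(s)
  pair <- auto_circadian_pair(d)
  expect_equal(pair, c(2L, 3L))
  for (k in pair) {
    p <- estimate_component_period(ssa_components(d, k)[, 1])
    expect_equal(p, 1440, tolerance = 0.1)
  }
})
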