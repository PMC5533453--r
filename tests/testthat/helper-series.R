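# Fixture builders shared across the suite.

# plain tibble series from a numeric vector (1-min epochs, midnight start)
as_series <- function(x, epoch = 1, start = 0) {
  tibble::tibble(time_min = start + (seq_along(x) - 1) * epoch, counts = x)
}

# noise-free constant-parameter cosine subject spec
noisefree_spec <- function(...) {
  cohort_spec(n_subjects = 1, mesor_sd = 0, amplitude_day_cv = 0,
              acrophase_day_sd = 0, noise_scale = 0,
              integer_counts = FALSE, ...)
}

# cosine series with per-day acrophases (minutes of day) injected exactly
piecewise_cosine <- function(acro_min_by_day, mesor = 216, amplitude = 178,
                             period = 1440) {
  n_days <- length(acro_min_by_day)
  t <- 0:(n_days * 1440 - 1)
  day <- pmin(floor(t / 1440), n_days - 1) + 1
  as_series(mesor + amplitude * cos(2 * pi * (t - acro_min_by_day[day]) / period))
}

# independent brute-force SSA on small series: dense Hankel built by loops,
# base svd(), naive per-element diagonal averaging
ssa_oracle <- function(x, L) {
  n <- length(x)
  K <- n - L + 1
  X <- matrix(0, K, L)
  for (i in 1:K) for (j in 1:L) X[i, j] <- x[i + j - 1]
  sv <- svd(X)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  comps <- matrix(0, n, r)
  for (k in 1:r) {
    E <- sv$d[k] * outer(sv$u[, k], sv$v[, k])
    g <- numeric(n)
    for (m in 1:n) {
      vals <- c()
      for (i in 1:K) {
        j <- m - i + 1
        if (j >= 1 && j <= L) vals <- c(vals, E[i, j])
      }
      g[m] <- mean(vals)
    }
    comps[, k] <- g
  }
  list(d = sv$d[1:r], comps = comps)
}

# coarse-to-fine grid search oracle for the cosinor optimum
cosinor_grid_oracle <- function(t, x, period, resolution = 1e-3) {
  sse <- function(M, A, phi) sum((x - (M + A * cos(2 * pi * t / period + phi)))^2)
  M0 <- mean(x); A0 <- diff(range(x)) / 2
  lims <- list(M = c(M0 - A0, M0 + A0), A = c(0, 2 * A0), phi = c(-pi, pi))
  best <- c(M = M0, A = A0 / 2, phi = 0)
  repeat {
    grids <- lapply(names(lims), function(p) seq(lims[[p]][1], lims[[p]][2], length.out = 21))
    names(grids) <- names(lims)
    cand <- expand.grid(grids)
    errs <- mapply(sse, cand$M, cand$A, cand$phi)
    best <- unlist(cand[which.min(errs), ])
    widths <- vapply(lims, diff, numeric(1))
    if (all(widths / 20 < resolution / 2)) break
    lims <- lapply(names(lims), function(p) {
      w <- diff(lims[[p]]) / 20
      c(best[[p]] - 2 * w, best[[p]] + 2 * w)
    })
    names(lims) <- c("M", "A", "phi")
  }
  best
}
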