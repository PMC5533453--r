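# Singular spectrum analysis: Hankel embedding of the series, singular
# value decomposition of the trajectory matrix, and diagonal averaging of
# the rank-1 elementary matrices back into additive time-series components
#   x(n) = sum_k sigma_k g_k(n).
# The SVD is computed from the L x L symmetric eigenproblem of t(X) %*% X,
# and left singular vectors are recovered as u_k = X v_k / sigma_k, which
# keeps the reconstruction exact (sum_k sigma_k u_k v_k' = X V V' = X) and
# scales to week-long 1-min series at L = 1440.  Diagonal averaging of a
# rank-1 matrix u v' is the convolution of u and v divided by the
# anti-diagonal lengths, evaluated by FFT.

#' Hankel trajectory matrix of a series
#'
#' Row i of the K x L matrix is the lagged window (x_i, ..., x_(i+L-1)),
#' K = N - L + 1, so element \[i, j\] = x\[i + j - 1\] and every ascending
#' anti-diagonal is constant.
#'
#' @param x Numeric vector.
#' @param L Window length (embedding dimension), 2 <= L <= N/2.
#' @return A K x L numeric matrix.
#' @export
ssa_embed <- function(x, L) {
  n <- length(x)
  if (L < 2 || L > n / 2) stop("window length must satisfy 2 <= L <= N/2", call. = FALSE)
  L <- as.integer(L)
  K <- n - L + 1L
  matrix(x[outer(seq_len(K), 0:(L - 1L), "+")], K, L)
}

#' Diagonal (anti-diagonal) averaging of a matrix into a series
#'
#' The n-th output value is the mean of all entries with row + col - 1 = n;
#' for a Hankel matrix this inverts [ssa_embed()] exactly.
#'
#' @param m A K x L numeric matrix.
#' @return Numeric vector of length K + L - 1.
#' @export
diagonal_average <- function(m) {
  idx <- as.vector(row(m) + col(m) - 1L)
  sums <- rowsum(as.vector(m), idx)
  as.numeric(sums / diag_weights(nrow(m), ncol(m)))
}

# number of entries on each ascending anti-diagonal of a K x L matrix
diag_weights <- function(K, L) {
  n <- K + L - 1L
  pmin(seq_len(n), L, K, n - seq_len(n) + 1L)
}

#' Singular spectrum decomposition of an actigraphy series
#'
#' @param data Single-subject actigraphy tibble (or a bare numeric vector,
#'   taken as a 1-min epoch series starting at midnight).
#' @param L Window length in samples (default 1440, i.e. 24 h at 1-min
#'   epochs); must satisfy 2 <= L <= N/2.  Oscillations with period up to
#'   about L samples are resolved into separate components; slower ones are
#'   absorbed in the trend.
#' @param r_max Maximum number of retained components (default 1000; the
#'   effective rank may be smaller).  Partial variances `lambda_tot` always
#'   account for the full rank, so truncation never distorts scree
#'   fractions.
#' @return An object of class `ssa_decomp` with singular values `sigma`,
#'   partial variances `lambda`, `lambda_tot`, window `L`, `K = N - L + 1`
#'   and the right singular vectors.  Component series are materialised on
#'   demand by [ssa_components()] / [ssa_reconstruct()].
#' @examples
#' d <- ssa_decompose(sin(2 * pi * (0:575) / 96), L = 96)
#' ssa_scree(d)[1:3, ]
#' @export
ssa_decompose <- function(data, L = 1440, r_max = 1000) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- tibble::tibble(time_min = seq_along(data) - 1, counts = data)
  }
  info <- series_info(data)
  X <- ssa_embed(info$x, L)
  K <- nrow(X); L <- ncol(X)
  ev <- eigen(crossprod(X), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  lambda_tot <- sum(lam)
  tol <- max(lam) * 1e-14
  r <- min(sum(lam > tol), r_max, K, L)
  if (r < 1L) stop("zero series has no SSA components", call. = FALSE)
  structure(list(
    x = info$x, time_min = info$time_min,
    epoch_minutes = info$epoch_minutes, start_clock = info$start_clock,
    subject_id = if ("subject_id" %in% names(data)) data$subject_id[1] else NA_character_,
    group = if ("group" %in% names(data)) data$group[1] else NA_character_,
    N = info$n, L = L, K = K, r = r,
    sigma = sqrt(lam[seq_len(r)]),
    lambda = lam[seq_len(r)],
    lambda_tot = lambda_tot,
    v = ev$vectors[, seq_len(r), drop = FALSE]
  ), class = "ssa_decomp")
}

#' Unit-weight component series of a decomposition
#'
#' Returns the diagonally averaged components g_k(n) such that
#' `x = components %*% sigma` over the full rank; the physical contribution
#' of component k is `sigma\[k\] * g_k`.
#'
#' @param d An `ssa_decomp`.
#' @param k Integer vector of component indices (default all retained).
#' @return An N x length(k) matrix, one column per component.
#' @export
ssa_components <- function(d, k = seq_len(d$r)) {
  stopifnot(inherits(d, "ssa_decomp"), all(k >= 1), all(k <= d$r))
  X <- ssa_embed(d$x, d$L)
  U <- X %*% d$v[, k, drop = FALSE]
  U <- sweep(U, 2, d$sigma[k], "/")
  n <- d$N
  pad <- function(m, len) rbind(m, matrix(0, len - nrow(m), ncol(m)))
  fu <- stats::mvfft(pad(U, n))
  fv <- stats::mvfft(pad(d$v[, k, drop = FALSE], n))
  g <- Re(stats::mvfft(fu * fv, inverse = TRUE)) / n
  g / diag_weights(d$K, d$L)
}

#' Reconstruct the series from a subset of components
#'
#' @inheritParams ssa_components
#' @return Numeric vector of length N: `sum_k sigma_k g_k(n)` over `k`.
#' @export
ssa_reconstruct <- function(d, k = seq_len(d$r)) {
  drop(ssa_components(d, k) %*% d$sigma[k])
}

#' Mean period of a component series from its zero crossings
#'
#' Zero crossings of the mean-centred series are located with linear
#' interpolation (exact zeros count as crossings) and the mean period is
#' twice the mean spacing between successive crossings.  Components with
#' fewer than 2 crossings are labelled trend (`Inf`).
#'
#' @param g Numeric component series.
#' @param epoch_minutes Epoch length P in minutes (default 1).
#' @return Mean period in minutes (`Inf` for trend-like components).
#' @export
estimate_component_period <- function(g, epoch_minutes = 1) {
  gc <- g - mean(g)
  n <- length(gc)
  if (!any(gc != 0)) return(Inf)
  idx <- which(gc[-n] * gc[-1] < 0)
  pos <- idx + gc[idx] / (gc[idx] - gc[idx + 1])
  zpos <- which(gc == 0)
  if (length(zpos)) zpos <- zpos[c(TRUE, diff(zpos) > 1)] # a zero run is one crossing
  pos <- sort(c(pos, zpos))
  if (length(pos) < 2) return(Inf)
  2 * mean(diff(pos)) * epoch_minutes
}

#' Scree table of ordered fractional partial variances
#'
#' @param d An `ssa_decomp`.
#' @param periods If `TRUE`, also estimate each component's mean period and
#'   label it trend / circadian / ultradian (circadian = period within 20%
#'   of 1440 min).
#' @return Tibble with columns `k`, `sigma`, `lambda`, `lambda_frac`, and
#'   when requested `mean_period_min`, `label`.
#' @export
ssa_scree <- function(d, periods = FALSE) {
  stopifnot(inherits(d, "ssa_decomp"))
  out <- tibble::tibble(
    k = seq_len(d$r), sigma = d$sigma, lambda = d$lambda,
    lambda_frac = d$lambda / d$lambda_tot
  )
  if (periods) {
    g <- ssa_components(d)
    p <- apply(g, 2, estimate_component_period, epoch_minutes = d$epoch_minutes)
    out$mean_period_min <- p
    out$label <- dplyr::case_when(
      !is.finite(p) ~ "trend",
      abs(p - 1440) <= 0.2 * 1440 ~ "circadian",
      p > 1440 ~ "trend",
      TRUE ~ "ultradian"
    )
  }
  class(out) <- c("ssa_scree", class(out))
  out
}

#' Weighted correlation matrix between reconstructed components
#'
#' Uses the standard SSA weights w_n = number of occurrences of x_n in the
#' trajectory matrix, i.e. `min(n, L, K, N - n + 1)`.  Rows for zero-norm
#' components are set to 0 and flagged in attribute `"zero_norm"`.
#'
#' @param d An `ssa_decomp`.
#' @param k Component indices (default the first `min(r, 30)`).
#' @return A symmetric length(k) x length(k) matrix with unit diagonal.
#' @export
ssa_wcor <- function(d, k = seq_len(min(d$r, 30))) {
  g <- ssa_components(d, k)
  w <- diag_weights(d$K, d$L)
  gw <- g * sqrt(w)
  ip <- crossprod(gw)
  nrm <- sqrt(diag(ip))
  zero <- nrm <= 0
  nrm[zero] <- 1
  out <- ip / tcrossprod(nrm)
  out[zero, ] <- 0
  out[, zero] <- 0
  diag(out)[!zero] <- 1
  attr(out, "zero_norm") <- which(zero)
  out
}

#' Locate the circadian component pair of a decomposition
#'
#' Returns the first nearly degenerate pair (relative gap
#' `|lambda_k - lambda_(k+1)| / lambda_k < 0.2`) whose two mean periods lie
#' within 20% of 1440 min; falls back to the conventional pair c(2, 3)
#' with a warning if no such pair is found among the leading components.
#'
#' @param d An `ssa_decomp`.
#' @param k_max Highest index considered for the first member of the pair.
#' @return Integer vector of length 2.
#' @export
auto_circadian_pair <- function(d, k_max = 12) {
  kmax <- min(k_max, d$r - 1)
  g <- ssa_components(d, seq_len(min(kmax + 1, d$r)))
  per <- apply(g, 2, estimate_component_period, epoch_minutes = d$epoch_minutes)
  for (k in seq_len(kmax)) {
    gap <- abs(d$lambda[k] - d$lambda[k + 1]) / d$lambda[k]
    ok <- gap < 0.2 &&
      all(is.finite(per[k:(k + 1)])) &&
      all(abs(per[k:(k + 1)] - 1440) <= 0.2 * 1440)
    if (ok) return(c(k, k + 1L))
  }
  warning("no near-degenerate circadian pair found; using components 2:3",
          call. = FALSE)
  c(2L, 3L)
}

#' @export
print.ssa_decomp <- function(x, ...) {
  cat(sprintf(
    "SSA decomposition: N = %d, L = %d, K = %d, r = %d components\n",
    x$N, x$L, x$K, x$r))
  cat(sprintf("  leading lambda/lambda_tot: %s\n",
              paste(signif(x$lambda[seq_len(min(4, x$r))] / x$lambda_tot, 3),
                    collapse = ", ")))
  invisible(x)
}
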