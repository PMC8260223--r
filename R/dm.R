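# Dirichlet-multinomial model for per-event isoform splits.
#
# Counts y_s for sample s (total n_s) over J candidates follow
# DM(n_s; pi, phi) with proportions pi (sum 1) and precision phi > 0:
# large phi recovers the multinomial, small phi adds overdispersion.

#' Dirichlet-multinomial log-likelihood
#'
#' Sum over samples of
#' `log C(n; y) + lgamma(phi) - lgamma(n + phi) +
#'  sum_j [lgamma(y_j + phi*pi_j) - lgamma(phi*pi_j)]`,
#' evaluated via log-gamma throughout. A zero `pi_j` with a positive count
#' yields `-Inf` (an impossible observation, not an error); a zero `pi_j`
#' with a zero count contributes nothing.
#'
#' @param y Count matrix, samples in rows, candidates in columns (a vector is
#'   taken as a single sample).
#' @param pi Proportion vector (non-negative, sums to 1).
#' @param phi Precision (> 0).
#' @return Scalar log-likelihood.
#' @export
dm_loglik <- function(y, pi, phi) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  stop_if_not(length(pi) == ncol(y), "length(pi) must match ncol(y)")
  stop_if_not(all(pi >= 0) && abs(sum(pi) - 1) < 1e-8,
              "pi must be non-negative and sum to 1")
  stop_if_not(phi > 0, "phi must be > 0")
  if (nrow(y) == 0) return(0)
  zero <- pi == 0
  if (any(zero)) {
    if (any(y[, zero, drop = FALSE] > 0)) return(-Inf)
    y <- y[, !zero, drop = FALSE]
    pi <- pi[!zero]
  }
  n <- rowSums(y)
  a <- phi * pi
  coef <- sum(lgamma(n + 1)) - sum(lgamma(y + 1))
  ya <- y + matrix(a, nrow = nrow(y), ncol = length(a), byrow = TRUE)
  coef + nrow(y) * lgamma(phi) - sum(lgamma(n + phi)) +
    sum(lgamma(ya)) - nrow(y) * sum(lgamma(a))
}

# Proportion estimate at fixed phi from the expected-proportion fixpoint
# (mean posterior Dirichlet proportion across samples), optionally polished
# by direct likelihood maximization. The fixpoint of
# pi = mean_s[(y_s + phi*pi) / (n_s + phi)] followed by normalization is
# linear in pi and solves in closed form: pi proportional to
# sum_s y_s / (n_s + phi).
fit_pi_at_phi <- function(y, phi, polish = FALSE) {
  n <- rowSums(y)
  keep <- n > 0
  yk <- y[keep, , drop = FALSE]
  nk <- n[keep]
  J <- ncol(y)
  w <- colSums(yk / (nk + phi))
  if (sum(w) == 0) w <- rep(1, J)
  pi <- w / sum(w)
  if (polish) {
    eps <- 1e-9
    if (J == 2) {
      opt <- optimize(function(p1) dm_loglik(y, c(p1, 1 - p1), phi),
                      interval = c(eps, 1 - eps), maximum = TRUE,
                      tol = 1e-10)
      cand <- c(opt$maximum, 1 - opt$maximum)
    } else {
      # additive log-ratio parameterization, Nelder-Mead
      theta0 <- log(pmax(pi[-J], eps) / max(pi[J], eps))
      fn <- function(theta) {
        e <- exp(c(theta, 0))
        -dm_loglik(y, e / sum(e), phi)
      }
      opt <- optim(theta0, fn, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
      e <- exp(c(opt$par, 0))
      cand <- e / sum(e)
    }
    if (dm_loglik(y, cand, phi) >= dm_loglik(y, pi, phi)) pi <- cand
  }
  pi
}

# Alternative-model profile log-likelihood at phi: per-condition pi fits.
profile_ll <- function(y_by_cond, phi, polish = FALSE) {
  pis <- lapply(y_by_cond, fit_pi_at_phi, phi = phi, polish = polish)
  ll <- sum(mapply(function(y, pi) dm_loglik(y, pi, phi), y_by_cond, pis))
  list(ll = ll, pis = pis)
}

#' Fit the Dirichlet-multinomial event model under null and alternative
#'
#' The alternative model gives each condition its own proportion vector with
#' a single shared precision `phi`; `phi` is profiled on a log grid and
#' refined by golden-section search, with proportions at each `phi` from an
#' expected-proportion fixpoint (polished by direct maximization at the
#' selected `phi`). The null model refits one common proportion vector at
#' the same `phi`, so the models are nested and the likelihood-ratio
#' statistic `2 * (llAlt - llNull)` (clipped at zero) is asymptotically
#' chi-squared with `(n_conditions - 1) * (n_candidates - 1)` degrees of
#' freedom.
#'
#' @param y_by_cond Named list of count matrices (samples x candidates), one
#'   per condition.
#' @param phi_grid Log-spaced precision grid for the profile search.
#' @return A `dm_fit` list: `pi` (per-condition matrix), `pi_null`, `phi`,
#'   `ll_alt`, `ll_null`, `lrt_stat`, `df`.
#' @export
dm_fit <- function(y_by_cond,
                   phi_grid = 10^seq(log10(0.5), log10(1e5), length.out = 15)) {
  stop_if_not(is.list(y_by_cond) && length(y_by_cond) >= 2,
              "need count matrices for >= 2 conditions")
  y_by_cond <- lapply(y_by_cond, function(y) {
    if (is.null(dim(y))) matrix(y, nrow = 1) else as.matrix(y)
  })
  if (all(vapply(y_by_cond, sum, numeric(1)) == 0)) {
    stop("all counts are zero; cannot fit", call. = FALSE)
  }
  stop_if_not(all(vapply(y_by_cond, function(y) any(rowSums(y) > 0),
                         logical(1))),
              "each condition needs >= 1 sample with positive total")
  J <- ncol(y_by_cond[[1]])

  ll_of <- function(lphi) profile_ll(y_by_cond, exp(lphi))$ll
  lgrid <- log(phi_grid)
  lls <- vapply(lgrid, ll_of, numeric(1))
  i <- which.max(lls)
  lo <- lgrid[max(1, i - 1)]
  hi <- lgrid[min(length(lgrid), i + 1)]
  # golden-section refinement on log(phi)
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- ll_of(c1); f2 <- ll_of(c2)
  for (it in seq_len(25)) {
    if (b - a < 1e-3) break
    if (f1 > f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- ll_of(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- ll_of(c2)
    }
  }
  phi <- exp((a + b) / 2)

  alt <- profile_ll(y_by_cond, phi, polish = TRUE)
  # the null model is maximized over its own parameters too (common pi and
  # its own precision), so the statistic compares two fully maximized
  # nested models
  y_all <- do.call(rbind, y_by_cond)
  null_of <- function(lphi) {
    ph <- exp(lphi)
    dm_loglik(y_all, fit_pi_at_phi(y_all, ph), ph)
  }
  lls0 <- vapply(lgrid, null_of, numeric(1))
  i0 <- which.max(lls0)
  a0 <- lgrid[max(1, i0 - 1)]; b0 <- lgrid[min(length(lgrid), i0 + 1)]
  c1 <- b0 - gr * (b0 - a0); c2 <- a0 + gr * (b0 - a0)
  f1 <- null_of(c1); f2 <- null_of(c2)
  for (it in seq_len(25)) {
    if (b0 - a0 < 1e-3) break
    if (f1 > f2) {
      b0 <- c2; c2 <- c1; f2 <- f1
      c1 <- b0 - gr * (b0 - a0); f1 <- null_of(c1)
    } else {
      a0 <- c1; c1 <- c2; f1 <- f2
      c2 <- a0 + gr * (b0 - a0); f2 <- null_of(c2)
    }
  }
  phi_null <- exp((a0 + b0) / 2)
  pi_null <- fit_pi_at_phi(y_all, phi_null, polish = TRUE)
  ll_null <- dm_loglik(y_all, pi_null, phi_null)
  lrt <- max(0, 2 * (alt$ll - ll_null))
  pi_mat <- do.call(rbind, alt$pis)
  rownames(pi_mat) <- names(y_by_cond)
  structure(list(pi = pi_mat, pi_null = pi_null, phi = phi,
                 ll_alt = alt$ll, ll_null = ll_null, lrt_stat = lrt,
                 df = (length(y_by_cond) - 1) * (J - 1)),
            class = "dm_fit")
}

#' @export
print.dm_fit <- function(x, ...) {
  cat(sprintf("dm_fit: phi=%.3g, LRT=%.3f (df=%d)\n", x$phi, x$lrt_stat, x$df))
  print(round(x$pi, 4))
  invisible(x)
}
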