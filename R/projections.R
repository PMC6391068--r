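#' Orientation class of a traced axon
#'
#' Classifies the initial axon direction by its angle to the oral direction:
#' oral when within 45 degrees of it, aboral when within 45 degrees of the
#' anti-oral direction, circumferential otherwise. The three sectors
#' partition `[0, 180]` degrees exactly.
#'
#' @param axon_vec Initial axon direction (non-zero 2-vector).
#' @param oral_axis Unit vector pointing orally.
#' @return `"oral"`, `"aboral"` or `"circumferential"`.
#' @export
classify_orientation <- function(axon_vec, oral_axis) {
  if (sum(axon_vec^2) == 0) stop("axon vector must be non-zero")
  if (sum(oral_axis^2) == 0) stop("oral_axis must be non-zero")
  cosang <- sum(axon_vec * oral_axis) /
    sqrt(sum(axon_vec^2) * sum(oral_axis^2))
  theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  eps <- 1e-9  # keep exact 45/135-degree vectors on their sector boundary
  if (theta <= 45 + eps) "oral" else if (theta >= 135 - eps) "aboral" else "circumferential"
}

gmm2_loglik <- function(x, p) {
  sum(log(p$w[1] * stats::dnorm(x, p$mu[1], p$sd[1]) +
          p$w[2] * stats::dnorm(x, p$mu[2], p$sd[2])))
}

gmm2_em <- function(x, init, max_iter = 500, tol = 1e-8) {
  p <- init
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- p$w[1] * stats::dnorm(x, p$mu[1], p$sd[1])
    d2 <- p$w[2] * stats::dnorm(x, p$mu[2], p$sd[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    n1 <- sum(g); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    p$mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    p$sd <- pmax(c(sqrt(sum(g * (x - p$mu[1])^2) / n1),
                   sqrt(sum((1 - g) * (x - p$mu[2])^2) / n2)), 1e-6)
    p$w <- c(n1, n2) / length(x)
    ll_new <- gmm2_loglik(x, p)
    if (is.finite(ll) && abs(ll_new - ll) < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(par = p, loglik = ll, iter = it)
}

#' Two-component Gaussian mixture fit of projection lengths
#'
#' Fits a two-component 1D Gaussian mixture by expectation-maximization with
#' multiple restarts (initialized by a median split of the data plus
#' per-restart jitter; the best restart by log-likelihood wins). Components
#' are ordered by mean. When the fit is bimodal, the trough is the argmin of
#' the fitted density on a 0.01 mm grid between the two component means. The
#' fit is flagged unimodal (degenerate) when the means are closer than the
#' larger component SD, or when the fitted density has no interior minimum
#' between the means (no clear trough); no trough is reported in either case.
#'
#' @param lengths Projection lengths (mm, > 0, at least 4 values).
#' @param restarts Number of EM restarts (default 10).
#' @param seed Integer seed for the restart jitter.
#' @return A `mixture_fit` list: `means`, `sds`, `weights`, `trough_mm`,
#'   `bimodal`, `converged`, `loglik`.
#' @export
fit_bimodal <- function(lengths, restarts = 10, seed = 1) {
  x <- as.numeric(lengths)
  if (length(x) < 4) stop("need at least 4 lengths to fit a two-component mixture")
  if (any(x <= 0)) stop("lengths must be > 0")
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(hi) == 0) hi <- lo
  base <- list(mu = c(mean(lo), mean(hi)),
               sd = rep(max(stats::sd(x) / 2, 1e-3), 2),
               w = c(0.5, 0.5))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- base
    if (r > 1) {
      jit <- withr_seed_rnorm(seed + r, 2) * stats::sd(x) / 4
      init$mu <- init$mu + jit
    }
    fit <- gmm2_em(x, init)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  p <- best$par
  ord <- order(p$mu)
  mu <- p$mu[ord]; sd <- p$sd[ord]; w <- p$w[ord]
  # bimodal only when the components are distinct AND the fitted density has
  # a genuine interior minimum (a clear trough) between the ordered means
  bimodal <- (mu[2] - mu[1]) >= max(sd)
  trough <- NA_real_
  if (bimodal && mu[2] - mu[1] > 0.02) {
    grid <- seq(mu[1], mu[2], by = 0.01)
    dens <- w[1] * stats::dnorm(grid, mu[1], sd[1]) +
            w[2] * stats::dnorm(grid, mu[2], sd[2])
    k <- which.min(dens)
    if (k > 1 && k < length(grid)) {
      trough <- grid[k]
    } else {
      bimodal <- FALSE
    }
  } else {
    bimodal <- FALSE
  }
  structure(list(
    means = mu, sds = sd, weights = w,
    trough_mm = trough, bimodal = bimodal,
    converged = best$iter < 500, loglik = best$loglik
  ), class = "mixture_fit")
}

# rnorm draws from a private RNG stream, leaving the global RNG untouched
withr_seed_rnorm <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> means %.3g / %.3g mm, sds %.3g / %.3g, weights %.2f / %.2f\n",
              x$means[1], x$means[2], x$sds[1], x$sds[2], x$weights[1], x$weights[2]))
  if (x$bimodal) cat(sprintf("  bimodal, trough at %.2f mm\n", x$trough_mm))
  else cat("  degenerate (components indistinct): no trough\n")
  invisible(x)
}

#' Split projection lengths at a cutoff
#'
#' Lengths strictly below the cutoff are "short"; lengths at or above it are
#' "long" (the cutoff itself is long).
#'
#' @param lengths Numeric lengths (mm).
#' @param cutoff_mm Positive cutoff (mm).
#' @return List with `short` and `long` numeric vectors.
#' @export
split_by_cutoff <- function(lengths, cutoff_mm) {
  if (cutoff_mm <= 0) stop("cutoff must be > 0")
  list(short = lengths[lengths < cutoff_mm], long = lengths[lengths >= cutoff_mm])
}

#' Chi-square comparison of two proportions
#'
#' 2x2 chi-square test of `k1/n1` vs `k2/n2`, without continuity correction
#' by default.
#'
#' @param k1,n1,k2,n2 Successes and totals (0 <= k <= n, n > 0).
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic` (chi-square), `p_value`, `df`.
#' @export
compare_proportions <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0) stop("totals must be > 0")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("need 0 <= k <= n")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
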