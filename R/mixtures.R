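#' Gaussian mixture model fitted by EM
#'
#' Maximum-likelihood fit of a K-component univariate Gaussian mixture
#' to apparent efficiencies by expectation-maximization. Latent bin
#' states are i.i.d. with probabilities pi_1..pi_K; conditional on
#' state k the apparent efficiency is N(mu_k, sigma_k^2). Components
#' are initialized by k-means, the best of `n_restarts` runs (by
#' log-likelihood) is returned, and components are reported sorted by
#' ascending mean. The per-iteration log-likelihood trace is kept so
#' that EM monotonicity is checkable.
#'
#' @param values numeric data (apparent efficiencies); needs at least K
#'   distinct values.
#' @param K number of components.
#' @param seed integer seed for initialization.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param n_restarts number of random restarts.
#' @return a `mixture_fit`: `weights`, `means`, `sds`, `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, `K`, `kind`.
#' @export
fit_gaussian_mixture <- function(values, K = 2L, seed = 1L, tol = 1e-6,
                                 max_iter = 1000L, n_restarts = 5L) {
  values <- as.numeric(values[is.finite(values)])
  if (length(unique(values)) < K)
    stop("need at least K distinct finite values")
  if (K == 1L) {
    mu <- mean(values); sdv <- sqrt(mean((values - mu)^2))
    ll <- sum(dnorm(values, mu, sdv, log = TRUE))
    return(structure(list(weights = 1, means = mu, sds = sdv,
                          loglik = ll, loglik_trace = ll,
                          iterations = 0L, converged = TRUE, K = 1L,
                          kind = "gaussian"),
                     class = "mixture_fit"))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    km <- suppressWarnings(kmeans(values, centers = K, nstart = 2L))
    fit <- tryCatch(
      gmm_em(values, km$centers[, 1], tol, max_iter),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    stop("all EM restarts degenerated; the data may have < K effective clusters")
  o <- order(best$means)
  structure(list(weights = best$weights[o], means = best$means[o],
                 sds = best$sds[o], loglik = best$loglik,
                 loglik_trace = best$loglik_trace,
                 iterations = best$iterations, converged = best$converged,
                 K = K, kind = "gaussian"),
            class = "mixture_fit")
}

gmm_em <- function(x, mu0, tol, max_iter) {
  K <- length(mu0)
  n <- length(x)
  mu <- as.numeric(mu0)
  sdv <- rep(sd(x) / K, K)
  w <- rep(1 / K, K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K),
                   function(k) log(w[k]) + dnorm(x, mu[k], sdv[k], log = TRUE),
                   numeric(n))
    m <- apply(logd, 1, max)
    ll <- sum(m + log(rowSums(exp(logd - m))))
    resp <- exp(logd - m)
    resp <- resp / rowSums(resp)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("component collapsed to zero weight")
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sdv <- sqrt(colSums(resp * outer(x, mu, "-")^2) / nk)
    if (any(sdv < 1e-6)) stop("component variance degenerated")
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = sdv, loglik = ll,
       loglik_trace = ll_trace, iterations = length(ll_trace),
       converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<%s mixture, K = %d, loglik = %.2f, %s after %d iterations>\n",
              x$kind, x$K, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (x$kind == "gaussian") {
    print(data.frame(weight = round(x$weights, 4),
                     mean = round(x$means, 4), sd = round(x$sds, 4)))
  } else {
    print(data.frame(weight = round(x$weights, 4),
                     xi = round(x$xi, 4), omega = round(x$omega, 4),
                     alpha = round(x$alpha, 3)))
  }
  invisible(x)
}

#' Skew-normal density
#'
#' \deqn{f(x) = \frac{2}{\omega} \phi\!\left(\frac{x-\xi}{\omega}\right)
#'   \Phi\!\left(\alpha \frac{x-\xi}{\omega}\right),}
#' with location `xi`, scale `omega` and shape `alpha`; `alpha = 0`
#' recovers the Gaussian. Apparent-efficiency peaks near 0 or 1 are
#' strongly skewed, which is what this family is used to capture.
#'
#' @param x numeric.
#' @param xi location.
#' @param omega scale; > 0.
#' @param alpha shape.
#' @param log return the log density.
#' @return density values.
#' @export
dskew_normal <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  z <- (x - xi) / omega
  ld <- log(2) - log(omega) + dnorm(z, log = TRUE) +
    pnorm(alpha * z, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' @rdname dskew_normal
#' @param n number of draws.
#' @details `rskew_normal()` draws via the half-normal stochastic
#'   representation \eqn{x = \xi + \omega(\delta |u_0| +
#'   \sqrt{1-\delta^2}\, u_1)} with \eqn{\delta = \alpha/\sqrt{1+\alpha^2}}.
#' @export
rskew_normal <- function(n, xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  xi + omega * (delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n))
}

#' Skew-Gaussian mixture fitted by EM
#'
#' K-component skew-normal mixture (see [dskew_normal()]) fitted by an
#' EM algorithm built on the hierarchical truncated-normal latent
#' representation: each observation is \eqn{x = \xi + \Delta t + e}
#' with \eqn{t} half-normal, \eqn{e \sim N(0, \Gamma)},
#' \eqn{\Delta = \omega\delta}, \eqn{\Gamma = \omega^2(1-\delta^2)}.
#' The E-step computes posterior moments of t (a truncated normal);
#' the M-step updates \eqn{(\xi, \Delta, \Gamma)} per component in
#' conditional-maximization sweeps, so the observed-data
#' log-likelihood is non-decreasing. Components are initialized from
#' data quantile groups and reported sorted by ascending location (for
#' apparent-efficiency data the lowest component is the donor-only
#' peak).
#'
#' @inheritParams fit_gaussian_mixture
#' @return a `mixture_fit` with elements `weights`, `xi`, `omega`,
#'   `alpha` (and `means` = component means for convenience).
#' @export
fit_skew_mixture <- function(values, K = 3L, seed = 1L, tol = 1e-6,
                             max_iter = 1000L, n_restarts = 5L) {
  values <- as.numeric(values[is.finite(values)])
  if (length(unique(values)) < K)
    stop("need at least K distinct finite values")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    fit <- tryCatch(skew_em(values, K, tol, max_iter, jitter = (r > 1L)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stop("all skew-mixture EM restarts degenerated")
  o <- order(best$xi)
  delta <- best$alpha[o] / sqrt(1 + best$alpha[o]^2)
  structure(list(weights = best$weights[o], xi = best$xi[o],
                 omega = best$omega[o], alpha = best$alpha[o],
                 means = best$xi[o] + best$omega[o] * delta * sqrt(2 / pi),
                 loglik = best$loglik, loglik_trace = best$loglik_trace,
                 iterations = best$iterations, converged = best$converged,
                 K = K, kind = "skew_gaussian"),
            class = "mixture_fit")
}

skew_em <- function(x, K, tol, max_iter, jitter = FALSE) {
  n <- length(x)
  qs <- quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  grp <- findInterval(x, filter_midpoints(qs)) + 1L
  xi <- vapply(split(x, grp), median, numeric(1))[as.character(seq_len(K))]
  xi[is.na(xi)] <- qs[is.na(xi)]
  om <- vapply(split(x, grp), function(v) max(sd(v), 1e-3),
               numeric(1))[as.character(seq_len(K))]
  om[is.na(om)] <- sd(x)
  if (jitter) {
    xi <- xi + rnorm(K, sd = sd(x) / 10)
    om <- om * exp(rnorm(K, sd = 0.2))
  }
  # alpha = 0 is a fixed point of the EM map, so the shape must start
  # away from zero: method-of-moments delta from each group's skewness
  alpha <- vapply(seq_len(K), function(k) {
    v <- x[grp == k]
    if (length(v) < 8L) return(1)
    g1 <- mean((v - mean(v))^3) / sd(v)^3
    a <- abs(g1)^(2 / 3)
    delta <- sqrt(pi / 2 * a / (a + ((4 - pi) / 2)^(2 / 3)))
    delta <- min(delta, 0.95)
    sign_g <- if (g1 >= 0) 1 else -1
    sign_g * delta / sqrt(1 - delta^2)
  }, numeric(1))
  alpha[!is.finite(alpha) | alpha == 0] <- 1
  if (jitter) alpha <- alpha * exp(rnorm(K, sd = 0.3))
  w <- rep(1 / K, K)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k)
      log(w[k]) + dskew_normal(x, xi[k], om[k], alpha[k], log = TRUE),
      numeric(n))
    mrow <- apply(logd, 1, max)
    ll <- sum(mrow + log(rowSums(exp(logd - mrow))))
    resp <- exp(logd - mrow)
    resp <- resp / rowSums(resp)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("component collapsed to zero weight")
    w <- nk / n

    for (k in seq_len(K)) {
      delta <- alpha[k] / sqrt(1 + alpha[k]^2)
      Dl <- om[k] * delta
      Gm <- om[k]^2 * (1 - delta^2)
      # posterior of the half-normal latent t given x (truncated normal)
      s2 <- Gm / (Gm + Dl^2)
      mpost <- Dl * (x - xi[k]) / (Gm + Dl^2)
      spost <- sqrt(s2)
      h <- mpost / spost
      mills <- exp(dnorm(h, log = TRUE) - pnorm(h, log.p = TRUE))
      et <- mpost + spost * mills
      et2 <- mpost^2 + s2 + mpost * spost * mills
      rk <- resp[, k]
      sw <- nk[k]
      xi[k] <- sum(rk * (x - Dl * et)) / sw
      d <- x - xi[k]
      Dl <- sum(rk * et * d) / sum(rk * et2)
      Gm <- sum(rk * (d^2 - 2 * Dl * d * et + Dl^2 * et2)) / sw
      if (!is.finite(Gm) || Gm < 1e-10) stop("scale degenerated")
      om[k] <- sqrt(Gm + Dl^2)
      alpha[k] <- Dl / sqrt(Gm)
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(weights = w, xi = xi, omega = om, alpha = alpha, loglik = ll,
       loglik_trace = ll_trace, iterations = length(ll_trace),
       converged = converged)
}

filter_midpoints <- function(q) {
  if (length(q) < 2L) return(numeric(0))
  (q[-1] + q[-length(q)]) / 2
}
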