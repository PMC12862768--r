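#' Multi-sequence Gaussian hidden Markov model
#'
#' Baum--Welch fit of a K-state HMM with Gaussian emissions to a
#' collection of independent sequences sharing one parameter set -- the
#' natural model for per-burst-region apparent-efficiency series in
#' freely diffusing smFRET, where each focal-spot transit yields a
#' short independent time series. Every sequence contributes to the
#' shared initial distribution, transition matrix and emission
#' parameters; length-1 sequences inform the initial distribution and
#' emissions only. State means are initialized at the 25th/75th
#' percentiles (interior quantiles for K > 2) with uniform transitions,
#' and states are reported sorted by ascending mean.
#'
#' @param sequences list of numeric vectors (>= 2 sequences).
#' @param K number of hidden states.
#' @param seed integer seed (initialization is deterministic; the seed
#'   only matters if restarts are added by the caller).
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return an `hmm_fit`: `transition` (K x K), `means`, `variances`,
#'   `initial`, `loglik`, `loglik_trace`, `converged`, `iterations`,
#'   `n_sequences`, `mean_length`.
#' @export
fit_hmm <- function(sequences, K = 2L, seed = 1L, tol = 1e-6,
                    max_iter = 500L) {
  sequences <- lapply(sequences, function(s) as.numeric(s[is.finite(s)]))
  sequences <- sequences[lengths(sequences) > 0L]
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  x_all <- unlist(sequences, use.names = FALSE)
  if (length(x_all) <= K) stop("total sequence length must exceed K")
  set.seed(seed)

  mu <- as.numeric(quantile(x_all, probs = (2 * seq_len(K) - 1) / (2 * K)))
  if (any(duplicated(mu))) mu <- mu + seq_len(K) * 1e-6
  v <- rep(max(var(x_all) / K, 1e-6), K)
  Tm <- matrix(1 / K, K, K)
  pi0 <- rep(1 / K, K)

  len1 <- which(lengths(sequences) == 1L)
  multi <- which(lengths(sequences) > 1L)
  x1 <- unlist(sequences[len1], use.names = FALSE)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ll <- 0
    pi_acc <- numeric(K)
    t_acc <- matrix(0, K, K)
    g_acc <- numeric(K)        # sum of state posteriors
    gx_acc <- numeric(K)       # sum of posterior * x
    gx2_acc <- numeric(K)      # sum of posterior * x^2

    if (length(len1)) {
      lb <- vapply(seq_len(K), function(k)
        log(pi0[k]) + dnorm(x1, mu[k], sqrt(v[k]), log = TRUE),
        numeric(length(x1)))
      mrow <- apply(lb, 1, max)
      ll <- ll + sum(mrow + log(rowSums(exp(lb - mrow))))
      g <- exp(lb - mrow); g <- g / rowSums(g)
      pi_acc <- pi_acc + colSums(g)
      g_acc <- g_acc + colSums(g)
      gx_acc <- gx_acc + colSums(g * x1)
      gx2_acc <- gx2_acc + colSums(g * x1^2)
    }

    for (si in multi) {
      x <- sequences[[si]]
      Tt <- length(x)
      B <- vapply(seq_len(K), function(k)
        dnorm(x, mu[k], sqrt(v[k])), numeric(Tt))
      B <- pmax(matrix(B, Tt, K), 1e-300)
      alpha <- matrix(0, Tt, K)
      cvec <- numeric(Tt)
      a <- pi0 * B[1, ]
      cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
      for (t in 2:Tt) {
        a <- (alpha[t - 1L, ] %*% Tm) * B[t, ]
        cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
      }
      beta <- matrix(0, Tt, K)
      beta[Tt, ] <- 1
      for (t in (Tt - 1L):1L) {
        beta[t, ] <- (Tm %*% (B[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
      }
      gam <- alpha * beta
      gam <- gam / rowSums(gam)
      ll <- ll + sum(log(cvec))
      pi_acc <- pi_acc + gam[1L, ]
      for (t in seq_len(Tt - 1L)) {
        xi_t <- (alpha[t, ] %o% (B[t + 1L, ] * beta[t + 1L, ])) * Tm /
          cvec[t + 1L]
        t_acc <- t_acc + xi_t
      }
      g_acc <- g_acc + colSums(gam)
      gx_acc <- gx_acc + colSums(gam * x)
      gx2_acc <- gx2_acc + colSums(gam * x^2)
    }

    pi0 <- pi_acc / sum(pi_acc)
    rs <- rowSums(t_acc)
    for (k in seq_len(K))
      Tm[k, ] <- if (rs[k] > 0) t_acc[k, ] / rs[k] else Tm[k, ]
    mu <- gx_acc / g_acc
    v <- pmax(gx2_acc / g_acc - mu^2, 1e-8)

    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  o <- order(mu)
  structure(list(transition = Tm[o, o, drop = FALSE], means = mu[o],
                 variances = v[o], initial = pi0[o], loglik = ll,
                 loglik_trace = ll_trace, converged = converged,
                 iterations = length(ll_trace),
                 n_sequences = length(sequences),
                 mean_length = mean(lengths(sequences)), K = K),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(
    "<Gaussian HMM: %d states, %d sequences (mean length %.2f), loglik %.2f, %s>\n",
    x$K, x$n_sequences, x$mean_length, x$loglik,
    if (x$converged) "converged" else "NOT converged"))
  cat("transition matrix:\n"); print(round(x$transition, 4))
  cat("state means:    ", paste(round(x$means, 4), collapse = ", "), "\n")
  cat("state variances:", paste(signif(x$variances, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate from a Gaussian HMM
#'
#' Generates independent sequences from a K-state Gaussian HMM --
#' the generate-and-refit oracle used to validate [fit_hmm()].
#'
#' @param n_sequences number of sequences.
#' @param lengths_ sequence lengths (recycled).
#' @param transition K x K stochastic matrix.
#' @param means,sds emission parameters.
#' @param initial initial state distribution (default uniform).
#' @return list of numeric vectors.
#' @export
simulate_hmm <- function(n_sequences, lengths_, transition, means, sds,
                         initial = NULL) {
  K <- length(means)
  if (is.null(initial)) initial <- rep(1 / K, K)
  lens <- rep_len(lengths_, n_sequences)
  lapply(seq_len(n_sequences), function(i) {
    Tt <- lens[i]
    s <- numeric(Tt)
    st <- sample.int(K, 1L, prob = initial)
    for (t in seq_len(Tt)) {
      s[t] <- rnorm(1L, means[st], sds[st])
      if (t < Tt) st <- sample.int(K, 1L, prob = transition[st, ])
    }
    s
  })
}
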