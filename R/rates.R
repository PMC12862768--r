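#' Berezhkovskii--Szabo transition rate between two wells
#'
#' Computes the interconversion rate for one-dimensional diffusive
#' dynamics on a double-well landscape,
#' \deqn{Q_{R \to P} = \left[
#'   \left(\int_{-\infty}^{x^*} e^{-\beta V} dx\right)
#'   \left(\int_R^P e^{\beta V} / D\, dx\right) \right]^{-1},}
#' where \eqn{x^*} is the barrier location, the first integral is the
#' reactant population and the second the diffusive resistance across
#' the barrier. The nominal lower limit \eqn{-\infty} is truncated where
#' the integrand falls below 1e-12 of its maximum (the coordinate is a
#' distance, so the truncation error is far below quadrature tolerance
#' for any well of interest). With `D_conf` in A^2/ns the rate is
#' returned in 1/ms.
#'
#' @inheritParams partition_function
#' @param D_conf conformational diffusion coefficient, A^2/ns; > 0.
#' @param barrier_location barrier top \eqn{x^*}, A; must lie between the
#'   reactant and product anchors.
#' @param reactant,product anchor of each well, A: either a single point
#'   (typically the well minimum) or an interval within which the
#'   minimum of V is located numerically.
#' @return rate, 1/ms.
#' @export
bs_transition_rate <- function(landscape, thermo, D_conf, barrier_location,
                               reactant, product) {
  stopifnot(inherits(landscape, "fel"), inherits(thermo, "thermo_state"))
  stopifnot_scalar(D_conf, "D_conf", positive = TRUE)
  stopifnot_scalar(barrier_location, "barrier_location")
  anchor <- function(x, name) {
    if (length(x) == 1L) return(x)
    if (length(x) == 2L)
      return(optimize(function(r) evaluate_potential(landscape, r),
                      interval = sort(x))$minimum)
    stop(sprintf("`%s` must be a point or an interval", name))
  }
  r_R <- anchor(reactant, "reactant")
  r_P <- anchor(product, "product")
  if (!(min(r_R, r_P) < barrier_location && barrier_location < max(r_R, r_P)))
    stop("`barrier_location` must lie between the reactant and product anchors")
  beta <- thermo$beta

  # Reactant population integral, truncated adaptively on the left.
  pop_f <- function(x) exp(-beta * evaluate_potential(landscape, x))
  probe <- seq(barrier_location - 50 * abs(barrier_location - r_R),
               barrier_location, length.out = 4096L)
  pv <- pop_f(probe)
  keep <- pv >= 1e-12 * max(pv)
  lower <- probe[which(keep)[1]]
  pop <- integrate(pop_f, lower, barrier_location,
                   rel.tol = 1e-10, subdivisions = 500L)
  if (!is.finite(pop$value) || pop$value <= 0)
    stop("reactant population integral did not converge (value ",
         pop$value, ")")

  # Diffusive resistance integral between the two anchors (ns/A).
  res_f <- function(x) exp(beta * evaluate_potential(landscape, x)) / D_conf
  res <- integrate(res_f, min(r_R, r_P), max(r_R, r_P),
                   rel.tol = 1e-10, subdivisions = 500L)
  if (!is.finite(res$value) || res$value <= 0)
    stop("resistance integral diverged (value ", res$value, ")")

  rate_per_ns <- 1 / (pop$value * res$value)
  rate_per_ns * 1e6
}

#' High-barrier Kramers rate for a double well
#'
#' Closed-form overdamped Kramers estimate
#' \deqn{q = \frac{\beta D}{2\pi} \sqrt{V''_{well} |V''_{barrier}|}
#'   \; e^{-\beta \Delta V},}
#' valid when \eqn{\beta \Delta V \gg 1}. Used as an independent check
#' on the quadrature rate in the high-barrier regime.
#'
#' @inheritParams bs_transition_rate
#' @return rate, 1/ms.
#' @export
kramers_rate <- function(landscape, thermo, D_conf) {
  stopifnot(inherits(landscape, "fel"))
  if (landscape$kind != "bistable")
    stop("kramers_rate() requires a bistable landscape")
  beta <- thermo$beta
  k <- landscape$k_bistable
  w <- landscape$well_offset
  k_well <- 2 * k * w^2          # V'' at the minima
  k_barrier <- k * w^2           # |V''| at the barrier top
  dv <- barrier_height(landscape)
  rate_per_ns <- beta * D_conf / (2 * pi) * sqrt(k_well * k_barrier) *
    exp(-beta * dv)
  rate_per_ns * 1e6
}

#' Transition probability matrix over a lag time
#'
#' \eqn{T(\tau) = \exp(\tau Q)} via the matrix exponential, where Q is a
#' rate matrix (rows sum to zero, non-negative off-diagonals, 1/ms) and
#' `tau` the lag between state-determination measurements in ms. For a
#' symmetric two-state Q with rate q the off-diagonal of T is
#' \eqn{(1 - e^{-2 q \tau})/2}, which serves as the closed-form check.
#' `tau` is deliberately a required argument: the transition matrix is
#' only defined relative to a lag, and no canonical lag exists.
#'
#' @param Q K x K rate matrix, 1/ms.
#' @param tau lag time, ms; >= 0.
#' @param barrier_location optional barrier location (A), carried along
#'   for reporting.
#' @return an object of class `rate_result` with elements `Q`, `tau`,
#'   `T` (stochastic matrix) and `barrier_location`.
#' @export
transition_matrix <- function(Q, tau, barrier_location = NA_real_) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || !is.numeric(Q))
    stop("`Q` must be a square numeric matrix")
  if (any(!is.finite(Q))) stop("`Q` must be finite")
  if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q)))))
    stop("rows of `Q` must sum to 0")
  if (any(Q[row(Q) != col(Q)] < 0))
    stop("off-diagonal entries of `Q` must be non-negative")
  stopifnot_scalar(tau, "tau")
  if (tau < 0) stop("`tau` must be >= 0")
  Tm <- as.matrix(Matrix::expm(Matrix::Matrix(tau * Q)))
  Tm <- pmin(pmax(Tm, 0), 1)
  Tm <- Tm / rowSums(Tm)
  dimnames(Tm) <- dimnames(Q)
  structure(list(Q = Q, tau = tau, T = Tm,
                 barrier_location = barrier_location),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate result: tau = %g ms>\nQ (1/ms):\n", x$tau))
  print(x$Q)
  cat("T(tau):\n")
  print(round(x$T, 6))
  invisible(x)
}

#' Compare two transition matrices
#'
#' Elementwise deviation summary between an estimated and a reference
#' stochastic matrix (e.g. an HMM estimate against the analytic matrix).
#'
#' @param T_est,T_ref stochastic matrices of equal shape (rows sum to 1,
#'   entries in \[0, 1\]).
#' @return list with `max_abs` and `mean_abs` deviations.
#' @export
compare_transition_matrices <- function(T_est, T_ref) {
  check <- function(Tm, name) {
    if (!is.matrix(Tm) || !is.numeric(Tm))
      stop(sprintf("`%s` must be a numeric matrix", name))
    if (any(Tm < -1e-10) || any(Tm > 1 + 1e-10) ||
        any(abs(rowSums(Tm) - 1) > 1e-6))
      stop(sprintf("`%s` is not a stochastic matrix", name))
  }
  check(T_est, "T_est"); check(T_ref, "T_ref")
  if (!all(dim(T_est) == dim(T_ref)))
    stop("transition matrices have different shapes")
  d <- abs(T_est - T_ref)
  list(max_abs = max(d), mean_abs = mean(d))
}
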