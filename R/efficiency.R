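#' FRET efficiency models
#'
#' A distance-to-efficiency model of the form
#' \deqn{E(r) = \frac{1}{1 + c\,(r/R_0)^n},}
#' parameterized by the Foerster radius `R0` (the distance at which the
#' classical model gives E = 0.5), the exponent `n` and the prefactor
#' `c`. Two named variants are provided: [forster_model()] is the
#' classical point-dipole sixth-power law (n = 6, c = 1), and
#' [heterogeneous_model()] is the flattened inverse-2.65 law
#' (n = 2.65, c = 0.975) used for conformationally heterogeneous
#' proteins, where restricted dye motion breaks the ideal isotropic
#' dipole assumptions.
#'
#' @param R0 Foerster radius, A; > 0.
#' @param exponent power-law exponent; > 0.
#' @param prefactor multiplicative constant; > 0.
#' @return an object of class `efficiency_model`.
#' @export
efficiency_model <- function(R0, exponent = 6, prefactor = 1) {
  stopifnot_scalar(R0, "R0", positive = TRUE)
  stopifnot_scalar(exponent, "exponent", positive = TRUE)
  stopifnot_scalar(prefactor, "prefactor", positive = TRUE)
  structure(list(R0 = R0, exponent = exponent, prefactor = prefactor),
            class = "efficiency_model")
}

#' @rdname efficiency_model
#' @export
forster_model <- function(R0) efficiency_model(R0, exponent = 6, prefactor = 1)

#' @rdname efficiency_model
#' @export
heterogeneous_model <- function(R0)
  efficiency_model(R0, exponent = 2.65, prefactor = 0.975)

#' @export
print.efficiency_model <- function(x, ...) {
  cat(sprintf("<efficiency model: E = 1/(1 + %g (r/%g)^%g)>\n",
              x$prefactor, x$R0, x$exponent))
  invisible(x)
}

#' Convert between dye--dye distance and FRET efficiency
#'
#' `efficiency_from_distance()` evaluates E(r), strictly decreasing in
#' r; `distance_from_efficiency()` is its exact inverse
#' \eqn{r = R_0 ((1/E - 1)/c)^{1/n}}, defined for E strictly inside
#' (0, 1). Donor-only molecules (E = 0) are represented at the
#' trajectory level, never by an infinite distance.
#'
#' @param model an [efficiency_model()].
#' @param r distances, A; >= 0.
#' @param E efficiencies strictly in (0, 1).
#' @return numeric vector of efficiencies in \[0, 1\], or distances in A.
#' @export
efficiency_from_distance <- function(model, r) {
  stopifnot(inherits(model, "efficiency_model"))
  if (any(r < 0)) stop("`r` must be >= 0")
  1 / (1 + model$prefactor * (r / model$R0)^model$exponent)
}

#' @rdname efficiency_from_distance
#' @export
distance_from_efficiency <- function(model, E) {
  stopifnot(inherits(model, "efficiency_model"))
  if (any(E <= 0 | E >= 1))
    stop("`E` must lie strictly inside (0, 1): E = 0 maps to infinite and E = 1 to zero distance")
  model$R0 * ((1 / E - 1) / model$prefactor)^(1 / model$exponent)
}

#' Change of variables between distance and efficiency densities
#'
#' Transforms a probability density given on a grid between distance
#' space and efficiency space using the exact Jacobian of the efficiency
#' model: \eqn{|dr/dE| = r / (n E (1 - E))} and its reciprocal. The
#' returned grid is sorted increasing; a normalized input density maps
#' onto a normalized output density (up to grid discretization).
#'
#' @param model an [efficiency_model()].
#' @param grid input grid (distances in A for `r_to_E`, efficiencies in
#'   (0, 1) for `E_to_r`).
#' @param values density values on `grid` (1/A, or 1/unit efficiency).
#' @param direction `"r_to_E"` or `"E_to_r"`.
#' @return list with elements `grid` and `values` in the target space.
#' @export
transform_density <- function(model, grid, values,
                              direction = c("r_to_E", "E_to_r")) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "efficiency_model"))
  if (length(grid) != length(values) || length(grid) < 4L)
    stop("`grid` and `values` must have equal length >= 4")
  n <- model$exponent
  if (direction == "r_to_E") {
    E <- efficiency_from_distance(model, grid)
    if (any(E > 1 - 1e-12) || any(E < 1e-12))
      warning("density support touches E = 0 or E = 1; transform truncated")
    jac <- grid / (n * E * (1 - E))            # |dr/dE|
    out_grid <- rev(E)                         # E(r) is decreasing
    out_val <- rev(values * jac)
  } else {
    E <- grid
    if (any(E <= 0 | E >= 1))
      stop("efficiency grid must lie strictly inside (0, 1)")
    r <- distance_from_efficiency(model, E)
    jac <- n * E * (1 - E) / r                 # |dE/dr|
    out_grid <- rev(r)
    out_val <- rev(values * jac)
  }
  list(grid = out_grid, values = out_val)
}
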