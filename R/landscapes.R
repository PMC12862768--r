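#' Thermodynamic state
#'
#' Bundles the inverse thermal energy `beta` = 1/(kB T) used by the
#' Langevin integrator and by all Boltzmann statistics. `beta` is the
#' authoritative quantity; the temperature label is informational only
#' (the two example conditions shipped with the package use
#' `beta = 1.339` and `beta = 1.679` (kcal/mol)^-1).
#'
#' @param beta inverse energy, (kcal/mol)^-1; must be > 0.
#' @param temperature optional temperature label in kelvin.
#' @return an object of class `thermo_state`.
#' @export
thermo_state <- function(beta, temperature = NULL) {
  stopifnot_scalar(beta, "beta", positive = TRUE)
  structure(list(beta = beta, temperature = temperature),
            class = "thermo_state")
}

#' One-dimensional free-energy landscapes
#'
#' Constructors for the parametric landscapes on which dye--dye distances
#' evolve. The harmonic well is
#' \deqn{V_H(r) = (k_H/2) (r - r_c)^2,}
#' the symmetric double well ("bistable") is
#' \deqn{V_B(r) = (k_B/4) ((r - r_C)^2 - W^2)^2,}
#' with minima at \eqn{r_C \pm W} and a barrier of height
#' \eqn{k_B W^4 / 4} at \eqn{r_C}. `k_bistable` is a force constant in
#' kcal/(mol A^4) -- deliberately named to avoid collision with the
#' Boltzmann constant. Tabulated landscapes interpolate linearly between
#' grid points.
#'
#' @param k,k_harmonic harmonic force constant, kcal/(mol A^2); > 0.
#' @param center well / barrier centre, A.
#' @param k_bistable bistable force constant, kcal/(mol A^4); > 0.
#' @param well_offset half-distance between the two minima, A; > 0.
#' @param grid strictly increasing distance grid, A.
#' @param values free energy at `grid`, kcal/mol.
#' @return an object of class `fel` (free-energy landscape).
#' @export
harmonic_landscape <- function(k, center) {
  stopifnot_scalar(k, "k", positive = TRUE)
  stopifnot_scalar(center, "center")
  structure(list(kind = "harmonic", k_harmonic = k, center = center),
            class = "fel")
}

#' @rdname harmonic_landscape
#' @export
bistable_landscape <- function(k_bistable, center, well_offset) {
  stopifnot_scalar(k_bistable, "k_bistable", positive = TRUE)
  stopifnot_scalar(center, "center")
  stopifnot_scalar(well_offset, "well_offset", positive = TRUE)
  structure(list(kind = "bistable", k_bistable = k_bistable,
                 center = center, well_offset = well_offset),
            class = "fel")
}

#' @rdname harmonic_landscape
#' @export
tabulated_landscape <- function(grid, values) {
  if (length(grid) != length(values) || length(grid) < 2L)
    stop("`grid` and `values` must have equal length >= 2")
  if (any(!is.finite(grid)) || any(!is.finite(values)))
    stop("tabulated landscape must be finite")
  if (any(diff(grid) <= 0))
    stop("tabulated `grid` must be strictly increasing")
  structure(list(kind = "tabulated", grid = as.numeric(grid),
                 values = as.numeric(values)),
            class = "fel")
}

#' @export
print.fel <- function(x, ...) {
  cat("<free-energy landscape:", x$kind, ">\n")
  switch(x$kind,
    harmonic = cat(sprintf("  k = %g kcal/(mol A^2), center = %g A\n",
                           x$k_harmonic, x$center)),
    bistable = cat(sprintf(
      "  k = %g kcal/(mol A^4), center = %g A, well offset = %g A (barrier %g kcal/mol)\n",
      x$k_bistable, x$center, x$well_offset, barrier_height(x))),
    tabulated = cat(sprintf("  %d grid points on [%g, %g] A\n",
                            length(x$grid), min(x$grid), max(x$grid))))
  invisible(x)
}

#' Evaluate a landscape and its gradient
#'
#' `evaluate_potential()` returns V(r) in kcal/mol; `evaluate_gradient()`
#' returns dV/dr in kcal/(mol A) -- analytic for the parametric kinds and
#' by central finite differences (step = local grid spacing) for
#' tabulated landscapes.
#'
#' @param landscape a [harmonic_landscape()], [bistable_landscape()] or
#'   [tabulated_landscape()].
#' @param r distances, A. Tabulated landscapes require `r` within the
#'   grid range.
#' @return numeric vector the length of `r`.
#' @export
evaluate_potential <- function(landscape, r) {
  stopifnot(inherits(landscape, "fel"))
  if (any(!is.finite(r))) stop("`r` must be finite")
  switch(landscape$kind,
    harmonic = landscape$k_harmonic / 2 * (r - landscape$center)^2,
    bistable = {
      dr2 <- (r - landscape$center)^2
      landscape$k_bistable / 4 * (dr2 - landscape$well_offset^2)^2
    },
    tabulated = {
      g <- landscape$grid
      if (any(r < g[1]) || any(r > g[length(g)]))
        stop(sprintf("r outside tabulated grid range [%g, %g]",
                     g[1], g[length(g)]))
      approx(g, landscape$values, xout = r)$y
    })
}

#' @rdname evaluate_potential
#' @export
evaluate_gradient <- function(landscape, r) {
  stopifnot(inherits(landscape, "fel"))
  if (any(!is.finite(r))) stop("`r` must be finite")
  switch(landscape$kind,
    harmonic = landscape$k_harmonic * (r - landscape$center),
    bistable = {
      dr <- r - landscape$center
      landscape$k_bistable * (dr^2 - landscape$well_offset^2) * dr
    },
    tabulated = {
      g <- landscape$grid
      if (any(r < g[1]) || any(r > g[length(g)]))
        stop(sprintf("r outside tabulated grid range [%g, %g]",
                     g[1], g[length(g)]))
      h <- median(diff(g))
      lo <- pmax(r - h, g[1])
      hi <- pmin(r + h, g[length(g)])
      (approx(g, landscape$values, xout = hi)$y -
         approx(g, landscape$values, xout = lo)$y) / (hi - lo)
    })
}

# Upper bound on |V''| over the region a trajectory plausibly visits;
# used for the integrator stiffness diagnostic.
max_curvature <- function(landscape) {
  switch(landscape$kind,
    harmonic = landscape$k_harmonic,
    # |V''| = k |3 dr^2 - W^2|, maximised at the edge of the sampled
    # region; bound it over [center - 2W, center + 2W].
    bistable = landscape$k_bistable * 11 * landscape$well_offset^2,
    tabulated = {
      v <- landscape$values; g <- landscape$grid
      h <- diff(g)
      if (length(v) < 3L) return(0)
      d2 <- abs(diff(v, differences = 2L) / (head(h, -1) * tail(h, -1)))
      max(d2)
    })
}

#' Barrier height of a bistable landscape
#'
#' Free-energy difference between the barrier top at the centre and
#' either minimum: \eqn{k_B W^4/4}. The shipped two-state example
#' (k = 1e-4, W = 15 A) has a barrier of 1.265625 kcal/mol.
#'
#' @inheritParams evaluate_potential
#' @return barrier height, kcal/mol.
#' @export
barrier_height <- function(landscape) {
  stopifnot(inherits(landscape, "fel"))
  if (landscape$kind != "bistable")
    stop("barrier_height() is defined for bistable landscapes only")
  landscape$k_bistable * landscape$well_offset^4 / 4
}

# Integration support for Boltzmann-weighted quadrature: a range outside
# which exp(-beta V) is utterly negligible.
boltzmann_support <- function(landscape, thermo) {
  beta <- thermo$beta
  switch(landscape$kind,
    harmonic = {
      s <- sqrt(1 / (beta * landscape$k_harmonic))
      c(max(0, landscape$center - 12 * s), landscape$center + 12 * s)
    },
    bistable = {
      kw <- 2 * landscape$k_bistable * landscape$well_offset^2  # V'' at minima
      s <- sqrt(1 / (beta * kw))
      c(max(0, landscape$center - landscape$well_offset - 10 * s),
        landscape$center + landscape$well_offset + 10 * s)
    },
    tabulated = range(landscape$grid))
}

#' Partition function of a landscape
#'
#' \eqn{Z = \int_0^\infty e^{-\beta V(r)} dr} by adaptive quadrature
#' (kcal/mol energies, A distances; Z has units of A). Tabulated
#' landscapes integrate over their grid range.
#'
#' @inheritParams evaluate_potential
#' @param thermo a [thermo_state()].
#' @return partition function, A.
#' @export
partition_function <- function(landscape, thermo) {
  stopifnot(inherits(thermo, "thermo_state"))
  sup <- boltzmann_support(landscape, thermo)
  f <- function(r) exp(-thermo$beta * evaluate_potential(landscape, r))
  # restrict quadrature to where the integrand is non-negligible --
  # a wide tabulated grid that is essentially zero almost everywhere
  # otherwise triggers spurious roundoff failures
  probe <- seq(sup[1], sup[2], length.out = 4096L)
  pv <- f(probe)
  sig <- range(probe[pv >= 1e-13 * max(pv)])
  pad <- diff(sup) / 4096
  sup <- c(max(sup[1], sig[1] - pad), min(sup[2], sig[2] + pad))
  # piecewise-linear (tabulated) integrands can defeat adaptive
  # quadrature at tight tolerances; fall back to a dense trapezoid
  z <- tryCatch(
    integrate(f, sup[1], sup[2], rel.tol = 1e-10, subdivisions = 500L),
    error = function(e) {
      g <- seq(sup[1], sup[2], length.out = 262144L)
      v <- f(g)
      est <- sum((v[-1] + v[-length(v)]) / 2) * (g[2] - g[1])
      if (!is.finite(est))
        stop(sprintf(
          "partition-function quadrature failed on [%g, %g]: %s",
          sup[1], sup[2], conditionMessage(e)), call. = FALSE)
      list(value = est)
    })
  if (z$value <= 0 || !is.finite(z$value))
    stop("landscape is not normalizable (Z = ", z$value, ")")
  z$value
}

#' Boltzmann probability density of the dye--dye distance
#'
#' \eqn{P(r) = e^{-\beta V(r)} / Z} with Z from [partition_function()].
#' For the special case of two equal-weight harmonic populations use
#' [harmonic_pair_density()], which evaluates the closed form
#' \deqn{P(r) = \frac12 \sqrt{\beta k / 2\pi}\,
#'   (e^{-\beta V_{H1}(r)} + e^{-\beta V_{H2}(r)}).}
#'
#' @inheritParams partition_function
#' @param r distances, A.
#' @return probability density, 1/A.
#' @export
boltzmann_density <- function(landscape, thermo, r) {
  z <- partition_function(landscape, thermo)
  exp(-thermo$beta * evaluate_potential(landscape, r)) / z
}

#' @rdname boltzmann_density
#' @param k shared harmonic force constant, kcal/(mol A^2).
#' @param centers length-2 vector of well centres, A.
#' @export
harmonic_pair_density <- function(k, thermo, centers, r) {
  stopifnot(inherits(thermo, "thermo_state"), length(centers) == 2L)
  beta <- thermo$beta
  amp <- sqrt(beta * k / (2 * pi))
  0.5 * amp * (exp(-beta * k / 2 * (r - centers[1])^2) +
                 exp(-beta * k / 2 * (r - centers[2])^2))
}
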