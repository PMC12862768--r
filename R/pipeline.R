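#' Run the simulate-and-analyze pipeline
#'
#' Simulates a scenario, writes the photon stream, and runs the
#' standard analysis suite with the scenario's analysis settings:
#' millisecond binning and thresholding, a Gaussian mixture on the
#' above-threshold apparent efficiencies (plus a skew-Gaussian mixture
#' when requested), burst regions and the multi-sequence Gaussian HMM,
#' sliding-window burst search with size selection, and burst variance
#' analysis. All fitted parameters, seeds and scenario parameters are
#' echoed into a JSON report; burst and BVA tables are written as CSV
#' and two standard figures (efficiency histogram with the fitted
#' mixture, BVA density against the binomial reference) as PNG.
#'
#' @param scenario an `smfret_scenario`.
#' @param output_dir directory for outputs (created if needed).
#' @param seed root seed; defaults to the scenario's.
#' @param skew_K components for an optional skew-Gaussian mixture
#'   (`NULL` to skip).
#' @param plots write PNG figures.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(scenario, output_dir, seed = scenario$seed,
                         skew_K = NULL, plots = TRUE) {
  sc <- validate_scenario(scenario)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  an <- sc$analysis
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sim <- stage("simulate", simulate_experiment(sc, seed = seed))
  stage("write_photons",
        write_photons(sim$stream, file.path(output_dir, "photons.csv")))

  trace <- stage("bin", bin_photons(sim$stream, an$bin_width))
  mask <- threshold_bins(trace, an$threshold)
  eff <- trace$efficiency[mask]

  report <- list(
    scenario = sc$name, seed = seed,
    n_photons = length(sim$stream),
    n_bins = nrow(trace), n_bins_above_threshold = sum(mask),
    analysis = an,
    molecule_seeds = sim$ground_truth$seeds)

  if (sum(mask) >= 10) {
    gmm <- stage("gmm", fit_gaussian_mixture(eff, K = an$mixture_K,
                                             seed = seed))
    report$gmm <- gmm[c("weights", "means", "sds", "loglik", "converged")]
    if (!is.null(skew_K) && sum(mask) > 5 * skew_K) {
      skew <- stage("skew_gmm",
                    fit_skew_mixture(eff, K = skew_K, seed = seed))
      report$skew_gmm <- skew[c("weights", "xi", "omega", "alpha",
                                "means", "loglik", "converged")]
    }
    regions <- stage("regions", burst_regions(trace, an$threshold))
    report$burst_regions <- list(n = nrow(regions),
                                 mean_length = mean(regions$length))
    seqs <- region_sequences(regions)
    if (length(seqs) >= 2) {
      hmm <- stage("hmm", fit_hmm(seqs, K = an$hmm_K, seed = seed))
      report$hmm <- hmm[c("transition", "means", "variances",
                          "initial", "loglik", "converged")]
    }
  }

  bursts <- stage("burst_search",
                  sliding_window_burst_search(sim$stream, an$burst_window,
                                              an$burst_rate))
  sel <- select_bursts(bursts, an$burst_min_photons)
  report$bursts <- list(n_found = nrow(bursts), n_selected = nrow(sel))
  bva <- NULL
  if (nrow(sel) > 0) {
    data.table::fwrite(sel, file.path(output_dir, "bursts.csv"))
    bva <- stage("bva", burst_variance_analysis(sel, sim$stream, an$bva_n))
    data.table::fwrite(bva, file.path(output_dir, "bva.csv"))
    report$bva <- list(n_bursts = nrow(bva),
                       n_excluded = attr(bva, "n_excluded"))
  }

  if (plots) {
    if (sum(mask) >= 10)
      stage("plot_hist", ggplot2::ggsave(
        file.path(output_dir, "efficiency_histogram.png"),
        plot_efficiency_histogram(eff, report$gmm),
        width = 6, height = 4, dpi = 120))
    if (!is.null(bva) && nrow(bva) > 1)
      stage("plot_bva", ggplot2::ggsave(
        file.path(output_dir, "bva.png"),
        plot_bva(bva), width = 6, height = 4, dpi = 120))
  }

  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Efficiency histogram with a fitted Gaussian mixture
#'
#' @param eff apparent efficiencies.
#' @param gmm a fitted mixture (list with `weights`, `means`, `sds`),
#'   or `NULL` for the bare histogram.
#' @return a ggplot object.
#' @export
plot_efficiency_histogram <- function(eff, gmm = NULL) {
  df <- data.frame(eff = eff)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = eff)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey75", colour = "grey40") +
    ggplot2::labs(x = "apparent efficiency", y = "density") +
    ggplot2::xlim(-0.05, 1.05) +
    ggplot2::theme_minimal()
  if (!is.null(gmm)) {
    xg <- seq(0, 1, length.out = 400)
    dens <- rowSums(vapply(seq_along(gmm$means), function(k)
      gmm$weights[k] * dnorm(xg, gmm$means[k], gmm$sds[k]),
      numeric(length(xg))))
    p <- p + ggplot2::geom_line(
      data = data.frame(x = xg, y = dens),
      ggplot2::aes(x = x, y = y), linewidth = 0.8)
  }
  p
}

#' BVA scatter with the binomial reference curve
#'
#' @param bva a [burst_variance_analysis()] result.
#' @return a ggplot object.
#' @export
plot_bva <- function(bva) {
  n <- attr(bva, "n")
  xg <- seq(0.001, 0.999, length.out = 200)
  ggplot2::ggplot(bva, ggplot2::aes(x = mean_efficiency,
                                    y = sigma)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_density_2d(colour = "steelblue", na.rm = TRUE) +
    ggplot2::geom_line(data = data.frame(x = xg, y = bva_reference(xg, n)),
                       ggplot2::aes(x = x, y = y),
                       linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 0.45)) +
    ggplot2::labs(x = "burst mean apparent efficiency",
                  y = expression(sigma[i])) +
    ggplot2::theme_minimal()
}
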