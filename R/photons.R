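#' Photon timestamp streams
#'
#' A photon stream is the detector-level record of a simulation: integer
#' clock ticks (one tick = `tick` seconds, the engine step), the channel
#' that detected each photon (1 = donor, 2 = acceptor) and the emitting
#' molecule (0 = background). Timestamps are non-decreasing; several
#' photons may share a tick. Ticks are stored as doubles but are always
#' whole numbers well below 2^53, so the representation is exact.
#'
#' @param tick_index numeric vector of clock ticks (whole numbers).
#' @param channel integer vector, 1 (donor) or 2 (acceptor).
#' @param molecule_id integer vector; 0 marks background photons.
#' @param tick seconds per clock tick; > 0.
#' @param sorted set `TRUE` when the inputs are already in canonical
#'   order to skip the sort.
#' @return an object of class `photon_stream`.
#' @export
photon_stream <- function(tick_index, channel, molecule_id, tick,
                          sorted = FALSE) {
  stopifnot_scalar(tick, "tick", positive = TRUE)
  n <- length(tick_index)
  if (length(channel) != n)
    stop("`channel` must match `tick_index` in length")
  if (length(molecule_id) == 1L) molecule_id <- rep.int(molecule_id, n)
  if (length(molecule_id) != n)
    stop("`molecule_id` must match `tick_index` in length")
  channel <- as.integer(channel)
  if (n > 0 && (anyNA(channel) || any(channel < 1L | channel > 2L)))
    stop("`channel` must be 1 (donor) or 2 (acceptor) for every photon")
  if (!sorted && n > 1L) {
    o <- order(tick_index, channel, molecule_id)
    tick_index <- tick_index[o]
    channel <- channel[o]
    molecule_id <- molecule_id[o]
  }
  structure(list(tick_index = as.numeric(tick_index), channel = channel,
                 molecule_id = as.integer(molecule_id), tick = tick),
            class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  n <- length(x$tick_index)
  dur <- if (n) (max(x$tick_index) + 1) * x$tick else 0
  cat(sprintf(
    "<photon stream: %d photons (%d donor / %d acceptor), tick %.3g s, span %.3g s>\n",
    n, sum(x$channel == 1L), sum(x$channel == 2L), x$tick, dur))
  invisible(x)
}

#' @export
length.photon_stream <- function(x) length(x$tick_index)

#' Photon arrival times in seconds
#'
#' @param stream a [photon_stream()].
#' @return numeric vector, s.
#' @export
photon_times <- function(stream) {
  stopifnot(inherits(stream, "photon_stream"))
  stream$tick_index * stream$tick
}

#' Merge photon streams
#'
#' Concatenates streams recorded on the same clock and restores the
#' canonical order (tick, then channel, then molecule id -- a
#' deterministic tie-break for photons sharing a tick).
#'
#' @param streams list of [photon_stream()] objects with identical
#'   `tick` values.
#' @return a single `photon_stream`.
#' @export
merge_streams <- function(streams) {
  stopifnot(is.list(streams), length(streams) >= 1L)
  for (s in streams) stopifnot(inherits(s, "photon_stream"))
  ticks <- vapply(streams, function(s) s$tick, numeric(1))
  if (any(abs(ticks - ticks[1]) > 0))
    stop("cannot merge streams with different tick values")
  photon_stream(
    unlist(lapply(streams, `[[`, "tick_index"), use.names = FALSE),
    unlist(lapply(streams, `[[`, "channel"), use.names = FALSE),
    unlist(lapply(streams, `[[`, "molecule_id"), use.names = FALSE),
    tick = ticks[1])
}

#' Write / read photon streams
#'
#' Lossless plain-text round-trip: a one-line metadata header holding
#' the clock resolution, followed by a CSV table of
#' `tick,channel,molecule_id`.
#'
#' @param stream a [photon_stream()].
#' @param path file path.
#' @return `read_photons()` returns a `photon_stream`.
#' @export
write_photons <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  header <- sprintf("#smfretsim-photons tick=%.17g", stream$tick)
  con <- file(path, "w")
  writeLines(c(header, "tick,channel,molecule_id"), con)
  close(con)
  data.table::fwrite(
    data.table::data.table(tick = stream$tick_index,
                           channel = stream$channel,
                           molecule_id = stream$molecule_id),
    path, append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_photons
#' @export
read_photons <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#smfretsim-photons tick=([0-9.eE+-]+)$",
                                  header))[[1]]
  if (length(m) != 2L)
    stop("not a photon file (missing metadata header): ", path)
  tick <- as.numeric(m[2])
  tab <- data.table::fread(path, skip = 1L)
  if (!all(c("tick", "channel", "molecule_id") %in% names(tab)))
    stop("malformed photon file: ", path)
  photon_stream(tab$tick, tab$channel, tab$molecule_id, tick = tick,
                sorted = FALSE)
}
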