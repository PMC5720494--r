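# Seeded generators of synthetic rhythmic data.  They emulate
# bioluminescence-style dense traces and sparse RT-qPCR time courses
# (one circadian cycle sampled at 3-h intervals) so that every rhythm
# metric and regression fit is testable against known ground truth.

#' Specification of a synthetic rhythmic trace
#'
#' @param period oscillation period (hours).
#' @param amplitude initial cosine amplitude.
#' @param mesor baseline level.
#' @param damping exponential damping rate (1/h).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param dt sampling interval (hours).
#' @param duration total duration (hours).
#' @param phase phase offset (radians).
#' @param seed RNG seed; fixes the output exactly.
#' @return A \code{cc_trace_spec}.
#' @export
cc_trace_spec <- function(period = 24, amplitude = 1, mesor = 0, damping = 0,
                          noise_sd = 0, dt = 0.1, duration = 120, phase = 0,
                          seed = 1) {
  stopifnot(period > 0, dt > 0, duration > 0, noise_sd >= 0, amplitude >= 0,
            damping >= 0)
  structure(as.list(environment()), class = "cc_trace_spec")
}

#' Generate a synthetic damped, noisy cosine trace
#'
#' \eqn{y(t) = mesor + amplitude e^{-damping t} cos(2 pi t / period + phase)
#' + N(0, noise_sd^2)}; deterministic for a given seed.
#'
#' @param spec a \code{\link{cc_trace_spec}}.
#' @return Data frame with columns \code{time}, \code{value} and the spec
#'   attached as attribute \code{"spec"}.
#' @export
make_trace <- function(spec) {
  stopifnot(inherits(spec, "cc_trace_spec"))
  t <- seq(0, spec$duration, by = spec$dt)
  clean <- spec$mesor + spec$amplitude * exp(-spec$damping * t) *
    cos(2 * pi * t / spec$period + spec$phase)
  noise <- if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    stats::rnorm(length(t), 0, spec$noise_sd)
  } else rep(0, length(t))
  out <- data.frame(time = t, value = clean + noise)
  attr(out, "spec") <- spec
  out
}

#' Generate a sparse sampled cosinor time course
#'
#' Emulates the RT-qPCR design of one circadian cycle harvested at 3-h
#' intervals: \code{n_samples} points spaced \code{dt} hours.
#'
#' @param spec a \code{\link{cc_trace_spec}} (its \code{dt}/\code{duration}
#'   are ignored).
#' @param n_samples number of samples (default 9).
#' @param dt sampling interval in hours (default 3).
#' @return Data frame with columns \code{time}, \code{value}.
#' @export
make_timecourse <- function(spec, n_samples = 9, dt = 3) {
  stopifnot(inherits(spec, "cc_trace_spec"), n_samples > 1, dt > 0)
  t <- seq(0, by = dt, length.out = n_samples)
  clean <- spec$mesor + spec$amplitude * exp(-spec$damping * t) *
    cos(2 * pi * t / spec$period + spec$phase)
  noise <- if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    stats::rnorm(length(t), 0, spec$noise_sd)
  } else rep(0, length(t))
  out <- data.frame(time = t, value = clean + noise)
  attr(out, "spec") <- spec
  out
}

#' Write a synthetic time course as the two-column CSV consumed by the
#' fitting operations
#'
#' @param trace data frame from \code{\link{make_trace}} or
#'   \code{\link{make_timecourse}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
cc_write_timecourse <- function(trace, path) {
  utils::write.csv(trace[, c("time", "value")], path, row.names = FALSE)
  invisible(path)
}
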