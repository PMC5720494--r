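# Rhythm metrics: peak detection, transient/limit-cycle period estimation,
# circadian-time phase mapping, cycle means, cosinor and polynomial fits.

#' Detect peaks in a uniformly sampled series
#'
#' Local maxima are located on the discrete grid and refined by quadratic
#' interpolation through the three samples around the argmax; plateaus are
#' resolved to their midpoint.  Peaks whose prominence (height above the
#' higher of the two flanking minima) is below \code{min_prominence} times
#' the series range are discarded.
#'
#' @param time,value the sampled series (uniform spacing).
#' @param min_prominence minimal relative prominence (fraction of the series
#'   range), default 0.05.
#' @return Numeric vector of refined peak times (empty if fewer than one
#'   qualifying peak).
#' @export
detect_peaks <- function(time, value, min_prominence = 0.05) {
  stopifnot(length(time) == length(value), length(time) >= 3)
  n <- length(value)
  rng <- diff(range(value))
  if (!is.finite(rng) || rng == 0) return(numeric())

  # measurement noise makes every excursion a candidate; estimate the noise
  # from second differences (var = 6 sigma^2 for white noise on a smooth
  # signal) and pre-smooth only when it is non-negligible, so that clean
  # ODE output is never altered
  if (n >= 15) {
    sigma_hat <- stats::median(abs(diff(value, differences = 2))) / 2.2
    if (is.finite(sigma_hat) && sigma_hat > 0.002 * rng) {
      w <- min(2L * (n %/% 30) + 1L, 15L)
      if (w >= 3) {
        value <- as.numeric(stats::filter(value, rep(1 / w, w), sides = 2))
        pad <- (w - 1L) %/% 2L
        value[seq_len(pad)] <- value[pad + 1L]
        value[(n - pad + 1L):n] <- value[n - pad]
        rng <- diff(range(value))
      }
    }
  }

  d <- diff(value)
  s <- sign(d)
  # carry the sign over flat stretches so plateaus register once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) < 0) + 1L   # local maxima (plateau right edge)
  idx <- idx[idx > 1 & idx < n]
  if (!length(idx)) return(numeric())

  # plateau midpoint: walk left over equal values
  peak_t <- numeric(0); peak_v <- numeric(0)
  dt <- time[2] - time[1]
  for (i in idx) {
    j <- i
    while (j > 1 && value[j - 1] == value[i]) j <- j - 1
    if (j < i) {                       # flat top -> midpoint
      tt <- (time[j] + time[i]) / 2
      vv <- value[i]
    } else {                           # quadratic refinement
      y1 <- value[i - 1]; y2 <- value[i]; y3 <- value[i + 1]
      den <- y1 - 2 * y2 + y3
      off <- if (den < 0) 0.5 * (y1 - y3) / den else 0
      off <- max(-0.5, min(0.5, off))
      tt <- time[i] + off * dt
      vv <- y2 - 0.25 * (y1 - y3) * off
    }
    peak_t <- c(peak_t, tt); peak_v <- c(peak_v, vv)
  }
  # prominence with extended bases: walk out from each candidate until a
  # higher sample (or the boundary); the base is the minimum over that
  # stretch.  Near-equal twin peaks then keep the higher twin instead of
  # both being discarded.
  keep <- logical(length(peak_t))
  for (k in seq_along(idx)) {
    i <- idx[k]
    jl <- i
    while (jl > 1 && value[jl - 1] <= value[i]) jl <- jl - 1
    jr <- i
    while (jr < n && value[jr + 1] <= value[i]) jr <- jr + 1
    lo_l <- min(value[jl:i])
    lo_r <- min(value[i:jr])
    prom <- peak_v[k] - max(lo_l, lo_r)
    keep[k] <- prom >= min_prominence * rng
  }
  peak_t[keep]
}

#' Transient period estimate
#'
#' The period statistic of the study: the mean of the three successive
#' peak-to-peak intervals among the first four peaks of the named species
#' after \code{onset}.  On the limit cycle the intervals are constant and
#' the statistic equals the limit-cycle period.
#'
#' @param traj a \code{cc_trajectory} (or a data frame with \code{time},
#'   \code{value} columns when \code{species} is missing).
#' @param species species name.
#' @param onset measure from the first peak at or after this time (hours).
#' @param min_prominence passed to \code{\link{detect_peaks}}.
#' @return Period in hours, or \code{NA} ("not defined") when fewer than
#'   four peaks are available after onset.
#' @export
estimate_period_transient <- function(traj, species = NULL, onset = 0,
                                      min_prominence = 0.05) {
  ser <- if (inherits(traj, "cc_trajectory")) cc_series(traj, species)
         else traj
  pk <- detect_peaks(ser$time, ser$value, min_prominence)
  pk <- pk[pk >= onset]
  if (length(pk) < 4) return(NA_real_)
  mean(diff(pk[1:4]))
}

#' Is a trajectory rhythmic?
#'
#' Rhythmicity requires at least four detected peaks with relative
#' prominence >= 5 % of the series range; conditions below that report a
#' "not defined" (ND) period.
#'
#' @inheritParams estimate_period_transient
#' @return Logical.
#' @export
is_rhythmic <- function(traj, species = NULL, onset = 0,
                        min_prominence = 0.05) {
  ser <- if (inherits(traj, "cc_trajectory")) cc_series(traj, species)
         else traj
  pk <- detect_peaks(ser$time, ser$value, min_prominence)
  sum(pk >= onset) >= 4
}

#' Peak phase in circadian time
#'
#' Maps the peak time of a species to circadian time (CT) by the affine map
#' that sends the Bmal mRNA peak to CT 21 and one period to 24 CT-hours.
#'
#' @param traj a \code{cc_trajectory} on the limit cycle.
#' @param species species name(s).
#' @param reference reference species (default \code{"Bmal"}) anchored at
#'   \code{ref_ct} (default 21).
#' @return Named numeric vector of CT phases in [0, 24), or \code{NA} for
#'   non-rhythmic species.
#' @export
peak_phase_ct <- function(traj, species, reference = "Bmal", ref_ct = 21) {
  stopifnot(inherits(traj, "cc_trajectory"))
  ref <- cc_series(traj, reference)
  pk_ref <- detect_peaks(ref$time, ref$value)
  if (length(pk_ref) < 4)
    stop("reference species `", reference, "` is not rhythmic")
  period <- mean(diff(pk_ref))
  t_ref <- pk_ref[1]
  out <- vapply(species, function(sp) {
    ser <- cc_series(traj, sp)
    pk <- detect_peaks(ser$time, ser$value)
    if (length(pk) < 4) return(NA_real_)
    (ref_ct + 24 * (pk[which(pk >= t_ref)[1]] - t_ref) / period) %% 24
  }, numeric(1))
  setNames(out, species)
}

#' Time-average over an integer number of periods
#'
#' The constitutive mean used for clamping: the species is averaged over the
#' largest whole number of periods available in the trajectory (trapezoidal
#' rule).  Non-rhythmic series are averaged over the full window.
#'
#' @param traj a \code{cc_trajectory}.
#' @param species species name.
#' @return Mean concentration.
#' @export
cycle_mean <- function(traj, species) {
  ser <- cc_series(traj, species)
  pk <- detect_peaks(ser$time, ser$value)
  if (length(pk) >= 2) {
    lo <- pk[1]; hi <- pk[length(pk)]
    sel <- ser$time >= lo & ser$time <= hi
    ser <- ser[sel, ]
  }
  tt <- ser$time; vv <- ser$value
  if (length(tt) < 2) return(mean(vv))
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2) / (tt[length(tt)] - tt[1])
}

#' Amplitude (peak-to-trough) of a species
#'
#' @param traj a \code{cc_trajectory}.
#' @param species species name.
#' @return Peak-to-trough amplitude over the trajectory.
#' @export
cc_amplitude <- function(traj, species) {
  v <- cc_series(traj, species)$value
  max(v) - min(v)
}

#' Summarise the rhythm of one or more species
#'
#' @param traj a \code{cc_trajectory}.
#' @param species species names (default: Bmal mRNA).
#' @param onset onset for the transient period statistic.
#' @return A data frame with one row per species: \code{species},
#'   \code{rhythmic}, \code{period} (NA = ND), \code{phase_ct},
#'   \code{amplitude}.
#' @export
rhythm_summary <- function(traj, species = "Bmal", onset = 0) {
  rhythmic <- vapply(species, function(sp) is_rhythmic(traj, sp, onset),
                     logical(1))
  period <- vapply(species, function(sp)
    estimate_period_transient(traj, sp, onset), numeric(1))
  phase <- rep(NA_real_, length(species))
  if (is_rhythmic(traj, "Bmal"))
    phase[rhythmic] <- peak_phase_ct(traj, species[rhythmic])
  amp <- vapply(species, function(sp) cc_amplitude(traj, sp), numeric(1))
  data.frame(species = species, rhythmic = rhythmic, period = period,
             phase_ct = round(phase, 2), amplitude = amp,
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Regression fits for sampled time courses
# ---------------------------------------------------------------------------

#' Cosinor (harmonic regression) fit
#'
#' Least-squares fit of \eqn{y = m + a cos(2 pi (t - phi) / T)}.  With
#' \code{period} given the fit is the standard linear cosinor
#' (\code{lm} on cos/sin regressors); with \code{period = NULL} the period
#' is profiled over a grid and polished by \code{optimise}.
#'
#' @param t,y sampled time course (t in hours, >= 6 samples).
#' @param period fixed period in hours, or \code{NULL} to estimate it.
#' @param period_range search range when the period is free.
#' @return List with \code{mesor}, \code{amplitude}, \code{acrophase}
#'   (hours in [0, period)), \code{period}, \code{sse}.
#' @export
fit_harmonic <- function(t, y, period = 24, period_range = c(18, 30)) {
  stopifnot(length(t) == length(y), length(t) >= 6)
  one <- function(T) {
    cc <- cos(2 * pi * t / T); ss <- sin(2 * pi * t / T)
    fit <- lm(y ~ cc + ss)
    b <- coef(fit)
    b[is.na(b)] <- 0
    list(mesor = unname(b[1]),
         amplitude = unname(sqrt(b[2]^2 + b[3]^2)),
         acrophase = unname((atan2(b[3], b[2]) * T / (2 * pi)) %% T),
         period = T, sse = sum(residuals(fit)^2))
  }
  if (!is.null(period)) {
    if (!is.finite(period) || period <= 0) stop("`period` must be > 0")
    return(one(period))
  }
  grid <- seq(period_range[1], period_range[2], length.out = 61)
  sses <- vapply(grid, function(T) one(T)$sse, numeric(1))
  Tbest <- grid[which.min(sses)]
  lo <- max(period_range[1], Tbest - diff(grid[1:2]))
  hi <- min(period_range[2], Tbest + diff(grid[1:2]))
  Topt <- stats::optimise(function(T) one(T)$sse, c(lo, hi))$minimum
  one(Topt)
}

#' Polynomial least-squares fit
#'
#' Fits a raw polynomial of the given degree, the descriptive fit used for
#' weakly-rhythmic time courses such as E2f and p53.
#'
#' @param t,y sampled time course (more samples than \code{degree}).
#' @param degree polynomial degree, default 4.
#' @return List with \code{coefficients} (intercept first) and \code{sse}.
#' @export
fit_polynomial <- function(t, y, degree = 4) {
  stopifnot(length(t) == length(y), length(t) > degree, degree >= 0)
  fit <- if (degree == 0) lm(y ~ 1) else lm(y ~ poly(t, degree, raw = TRUE))
  cf <- unname(coef(fit))
  cf[is.na(cf)] <- 0
  list(coefficients = cf, sse = sum(residuals(fit)^2))
}

#' Write rhythm summaries for a set of conditions
#'
#' @param summaries named list of data frames from
#'   \code{\link{rhythm_summary}}; names label the conditions.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
cc_write_summary <- function(summaries, path) {
  rows <- do.call(rbind, lapply(names(summaries), function(cond) {
    cbind(condition = cond, summaries[[cond]])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column time-course table
#'
#' Accepts external sampled time courses (hours, value) for the fitting
#' operations.
#'
#' @param path CSV path with two columns (time in hours, value).
#' @return Data frame with columns \code{time}, \code{value}.
#' @export
cc_read_timecourse <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("expected a two-column (hours, value) table")
  data.frame(time = df[[1]], value = df[[2]])
}
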