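# Numerical integration: adaptive Runge-Kutta (Dormand-Prince 4(5), the
# ode45 pairing) with rtol = atol = 1e-9 and a fixed 0.01 h output grid,
# matching the study conditions.  The right-hand side is compiled C.

#' Integrate the model over a time span
#'
#' Solves the 45-ODE system with an adaptive Runge-Kutta method
#' (Dormand-Prince 4(5)) under a static perturbation context, sampling the
#' solution on a fixed output grid.
#'
#' @param model a \code{cc_model}.
#' @param y0 named initial state (46 species); \code{NULL} uses the model's
#'   stored initial state.
#' @param t_span duration in hours (a single number; integration runs from 0
#'   to \code{t_span}).
#' @param ctx static perturbation context (\code{\link{cc_context}}); frozen
#'   species with enforced values are overwritten in \code{y0} before
#'   integration.
#' @param reltol,abstol relative/absolute error tolerances (default 1e-9).
#' @param out_dt output grid spacing in hours (default 0.01).
#' @param t0 time stamp of the first output row (bookkeeping only; the
#'   system is autonomous).
#' @return A \code{cc_trajectory}: list with \code{times}, \code{states}
#'   (time x 46 matrix) and \code{meta} (parameter hash, context, integrator
#'   settings).
#' @export
cc_integrate <- function(model, y0 = NULL, t_span, ctx = NULL,
                         reltol = 1e-9, abstol = 1e-9, out_dt = 0.01,
                         t0 = 0) {
  .cc_validate_model(model)
  if (is.null(ctx)) ctx <- cc_context()
  if (is.null(y0)) y0 <- model$init
  if (!is.null(names(y0))) y0 <- y0[.CC_SPECIES$name]
  stopifnot(length(y0) == .CC_N_SPECIES, all(is.finite(y0)))
  # tolerate integrator slack: clip tiny negatives, reject real ones
  if (any(y0 < -1e-6)) stop("initial state must be non-negative")
  y0 <- pmax(y0, 0)
  if (!is.numeric(t_span) || length(t_span) != 1 || t_span < 0)
    stop("`t_span` must be a single non-negative duration in hours")
  # enforce clamp/knockout values at segment start
  if (length(ctx$values)) y0[names(ctx$values)] <- ctx$values
  names(y0) <- .CC_SPECIES$name
  # RB1 pool conservation: RB1_N + RBE2F + RB1p_N = rb_tot
  rbt <- model$params[["rb_tot"]]
  bound <- y0[["RB1_N"]] + y0[["RBE2F"]]
  if (bound > rbt) {       # infeasible split: scale the bound forms down
    y0[["RB1_N"]] <- y0[["RB1_N"]] * rbt / bound
    y0[["RBE2F"]] <- y0[["RBE2F"]] * rbt / bound
    bound <- rbt
  }
  y0[["RB1p_N"]] <- rbt - bound

  if (t_span == 0) {
    states <- matrix(y0, nrow = 1, dimnames = list(NULL, .CC_SPECIES$name))
    return(.cc_trajectory(t0, states, model, ctx, reltol, abstol, out_dt))
  }
  times <- seq(0, t_span, by = out_dt)
  if (abs(times[length(times)] - t_span) > 1e-9)
    times <- c(times, t_span)
  sol <- deSolve::ode(
    y = unname(y0), times = times, func = "cc_derivs", parms = .cc_parvec(model, ctx),
    dllname = "circacycle", initfunc = "cc_initmod",
    method = "ode45", rtol = reltol, atol = abstol,
    maxsteps = 1e6
  )
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    tlast <- sol[nrow(sol), 1]
    ylast <- sol[nrow(sol), -1]
    worst <- .CC_SPECIES$name[which.max(abs(
      cc_rhs(tlast, setNames(pmax(ylast, 0), .CC_SPECIES$name), model, ctx)))]
    stop("integrator failure at t = ", format(tlast),
         " h (largest derivative: ", worst, ")")
  }
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- .CC_SPECIES$name
  if (any(!is.finite(states)))
    stop("non-finite values in trajectory; offending species: ",
         paste(.CC_SPECIES$name[colSums(!is.finite(states)) > 0], collapse = ", "))
  .cc_trajectory(sol[, 1] + t0, states, model, ctx, reltol, abstol, out_dt)
}

.cc_trajectory <- function(times, states, model, ctx, reltol, abstol, out_dt,
                           perturbations = list()) {
  structure(list(
    times = as.numeric(times),
    states = states,
    meta = list(
      param_hash = .cc_param_hash(model),
      ktt = ctx$ktt, kd_bmal = ctx$kd_bmal,
      frozen = names(ctx$frozen)[ctx$frozen],
      perturbations = perturbations,
      integrator = list(method = "ode45", reltol = reltol, abstol = abstol,
                        out_dt = out_dt)
    )
  ), class = "cc_trajectory")
}

.cc_param_hash <- function(model) {
  # cheap deterministic fingerprint of (params, ktt)
  v <- c(model$params, model$ktt)
  sprintf("%.8e", sum(v * seq_along(v)) + sum(v^2))
}

#' @export
print.cc_trajectory <- function(x, ...) {
  cat("<cc_trajectory> ", length(x$times), " samples, t = [",
      format(min(x$times)), ", ", format(max(x$times)), "] h, ",
      ncol(x$states), " species\n", sep = "")
  invisible(x)
}

#' Extract one species' time series from a trajectory
#'
#' @param traj a \code{cc_trajectory}.
#' @param species species name.
#' @return A data frame with columns \code{time} and \code{value}.
#' @export
cc_series <- function(traj, species) {
  stopifnot(inherits(traj, "cc_trajectory"), species %in% colnames(traj$states))
  data.frame(time = traj$times, value = traj$states[, species])
}

#' Run a full scenario: burn-in, scheduled perturbations, analysis window
#'
#' The unperturbed genotype is integrated for \code{burn_in} hours so that
#' the system reaches its limit cycle; the returned trajectory then starts
#' at time 0 (= end of burn-in) and perturbations are switched on at their
#' onsets by stopping and restarting the integrator, so the discontinuity
#' never sits inside an adaptive step.
#'
#' @param model a \code{cc_model}.
#' @param genotype \code{"WT"} or \code{"KO"} (Ink4a/Arf double knockout).
#' @param perturbations list of \code{\link{cc_perturbation}} objects.
#' @param horizon analysis horizon in hours after burn-in.
#' @param burn_in burn-in duration in hours (default 240, about ten periods).
#' @param out_dt output grid spacing (default 0.01 h).
#' @param reltol,abstol integrator tolerances.
#' @return A \code{cc_trajectory} covering [0, horizon].
#' @export
cc_run_scenario <- function(model, genotype = c("WT", "KO"),
                            perturbations = list(), horizon = 120,
                            burn_in = 240, out_dt = 0.01,
                            reltol = 1e-9, abstol = 1e-9) {
  genotype <- match.arg(genotype)
  if (inherits(perturbations, "cc_perturbation"))
    perturbations <- list(perturbations)
  base <- if (genotype == "KO") list(knockout_ink4a_arf()) else list()

  # burn-in under the genotype only, sparse output
  ctx0 <- .cc_fold_context(base)
  y0 <- model$init
  if (burn_in > 0) {
    burn <- cc_integrate(model, y0, burn_in, ctx0, reltol, abstol,
                         out_dt = max(out_dt, 0.5))
    y0 <- burn$states[nrow(burn$states), ]
  }

  onsets <- vapply(perturbations, function(s) s$onset, numeric(1))
  bounds <- sort(unique(c(0, onsets[onsets > 0 & onsets < horizon], horizon)))
  pieces <- list()
  for (i in seq_len(length(bounds) - 1)) {
    t1 <- bounds[i]; t2 <- bounds[i + 1]
    active <- perturbations[onsets <= t1]
    ctx <- .cc_fold_context(c(base, active))
    seg <- cc_integrate(model, y0, t2 - t1, ctx, reltol, abstol, out_dt,
                        t0 = t1)
    y0 <- seg$states[nrow(seg$states), ]
    # drop the duplicated boundary row of subsequent segments
    if (i > 1) {
      seg$times <- seg$times[-1]
      seg$states <- seg$states[-1, , drop = FALSE]
    }
    pieces[[i]] <- seg
  }
  if (!length(pieces)) {  # horizon == 0
    ctx <- .cc_fold_context(c(base, perturbations[onsets <= 0]))
    return(cc_integrate(model, y0, 0, ctx, reltol, abstol, out_dt))
  }
  traj <- .cc_trajectory(
    do.call(c, lapply(pieces, `[[`, "times")),
    do.call(rbind, lapply(pieces, `[[`, "states")),
    model, .cc_fold_context(c(base, perturbations)),
    reltol, abstol, out_dt,
    perturbations = c(base, perturbations))
  traj$meta$genotype <- genotype
  traj
}

#' Write a trajectory to disk
#'
#' Writes a wide CSV (time, one column per species), optionally a tidy
#' long-format CSV, and a JSON sidecar with the reproducibility metadata.
#'
#' @param traj a \code{cc_trajectory}.
#' @param path output CSV path; the JSON sidecar gets extension
#'   \code{.meta.json}.
#' @param long also write \code{<path base>_long.csv} in (time, species,
#'   value) format.
#' @return \code{path}, invisibly.
#' @export
cc_write_trajectory <- function(traj, path, long = FALSE) {
  stopifnot(inherits(traj, "cc_trajectory"))
  wide <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(wide, path, row.names = FALSE)
  if (long) {
    lng <- data.frame(
      time = rep(traj$times, ncol(traj$states)),
      species = rep(colnames(traj$states), each = length(traj$times)),
      value = as.vector(traj$states))
    utils::write.csv(lng, sub("\\.csv$", "_long.csv", path), row.names = FALSE)
  }
  meta <- traj$meta
  meta$perturbations <- lapply(meta$perturbations, unclass)
  jsonlite::write_json(meta, sub("\\.csv$", ".meta.json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
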