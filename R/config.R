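# Run configuration: schema-validated YAML round-tripping and the
# command-line dispatcher.

.CC_CONFIG_DEFAULTS <- list(
  model = NULL,                 # NULL = packaged calibrated model
  genotype = "WT",
  perturbations = list(),
  integrator = list(reltol = 1e-9, abstol = 1e-9, out_dt = 0.01,
                    burn_in = 240, horizon = 120),
  analysis = list(species = "Bmal", onset = 0),
  scan = list(ktt_grid = seq(0.4, 1, by = 0.1),
              onset_grid = seq(0, 22, by = 2), ktt = 0.7, ras_onset = 24),
  output_dir = ".",
  seed = 1L
)

#' Load and validate a run configuration
#'
#' Reads a YAML run config, rejects unknown keys, applies the documented
#' defaults and validates the perturbation specs.
#'
#' @param path YAML file path.
#' @return A \code{cc_config} list.
#' @export
cc_load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.CC_CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- .CC_CONFIG_DEFAULTS
  for (k in names(raw)) {
    if (k %in% c("integrator", "analysis", "scan")) {
      bad <- setdiff(names(raw[[k]]), names(.CC_CONFIG_DEFAULTS[[k]]))
      if (length(bad))
        stop("unknown config key(s) under `", k, "`: ",
             paste(bad, collapse = ", "))
      cfg[[k]] <- modifyList(cfg[[k]], raw[[k]])
    } else cfg[k] <- list(raw[[k]])   # keeps explicit-null keys present
  }
  if (!cfg$genotype %in% c("WT", "KO"))
    stop("config key `genotype` must be \"WT\" or \"KO\"")
  cfg$perturbations <- lapply(cfg$perturbations, function(sp) {
    do.call(cc_perturbation, sp[intersect(names(sp),
                                          c("kind", "onset", "magnitude",
                                            "target"))])
  })
  structure(cfg, class = "cc_config")
}

#' Save a run configuration
#'
#' Writes the fully resolved configuration (defaults filled in) so that a
#' run can be reproduced exactly; \code{load} then \code{save} is the
#' identity on resolved configs.
#'
#' @param cfg a \code{cc_config}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
cc_save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$perturbations <- lapply(cfg$perturbations, function(s)
    Filter(Negate(is.null), unclass(s)))
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

.cc_config_model <- function(cfg) {
  if (is.null(cfg$model)) cc_load_model() else cc_load_model(cfg$model)
}

#' Command-line entry point
#'
#' Dispatches the subcommands \code{simulate}, \code{scan-ktt},
#' \code{scan-onset}, \code{modular}, \code{sensitivity} and \code{phases}.
#' Every subcommand takes a run-config YAML as first positional argument
#' and writes CSV results, a JSON summary and the resolved config into the
#' configured output directory.  Exit codes: 0 success, 2 configuration
#' error, 3 numerical failure.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code, invisibly.
#' @export
cc_cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: circacycle <subcommand> <config.yaml>",
    "subcommands:",
    "  simulate     burn-in + scenario trajectory and rhythm summary",
    "  scan-ktt     RAS dose-response scan (period vs ktt)",
    "  scan-onset   period vs perturbation onset time",
    "  modular      modular-analysis battery (decouple/clamp x genotype)",
    "  sensitivity  parameter control coefficients",
    "  phases       circadian-time peak phases of the core-clock species",
    sep = "\n")
  if (!length(argv) || argv[1] %in% c("--help", "-h", "help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  sub <- argv[1]
  known <- c("simulate", "scan-ktt", "scan-onset", "modular", "sensitivity",
             "phases")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  if (length(argv) < 2) {
    message("missing config file\n", usage)
    return(invisible(2L))
  }
  cfg <- tryCatch(cc_load_config(argv[2]), error = function(e) e)
  if (inherits(cfg, "error")) {
    message("config error: ", conditionMessage(cfg))
    return(invisible(2L))
  }
  set.seed(cfg$seed)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  t0 <- Sys.time()
  res <- tryCatch({
    model <- .cc_config_model(cfg)
    it <- cfg$integrator
    switch(sub,
      simulate = {
        traj <- cc_run_scenario(model, cfg$genotype, cfg$perturbations,
                                horizon = it$horizon, burn_in = it$burn_in,
                                out_dt = it$out_dt, reltol = it$reltol,
                                abstol = it$abstol)
        cc_write_trajectory(traj, out("trajectory.csv"))
        summ <- rhythm_summary(traj, cfg$analysis$species,
                               onset = cfg$analysis$onset)
        utils::write.csv(summ, out("summary.csv"), row.names = FALSE)
        summ
      },
      `scan-ktt` = {
        sc <- ktt_scan(model, cfg$genotype, cfg$scan$ktt_grid,
                       onset = cfg$scan$ras_onset,
                       species = cfg$analysis$species,
                       burn_in = it$burn_in, out_dt = max(it$out_dt, 0.02))
        utils::write.csv(sc, out("ktt_scan.csv"), row.names = FALSE)
        sc
      },
      `scan-onset` = {
        sc <- onset_scan(model, cfg$genotype, cfg$scan$ktt,
                         cfg$scan$onset_grid, species = cfg$analysis$species,
                         burn_in = it$burn_in, out_dt = max(it$out_dt, 0.02))
        utils::write.csv(sc, out("onset_scan.csv"), row.names = FALSE)
        sc
      },
      modular = {
        mb <- modular_analysis_battery(model, cfg$scan$ktt_grid,
                                       onset = cfg$scan$ras_onset,
                                       burn_in = it$burn_in,
                                       out_dt = max(it$out_dt, 0.02))
        utils::write.csv(mb, out("modular.csv"), row.names = FALSE)
        mb
      },
      sensitivity = {
        cco <- control_coefficients(model, out_dt = max(it$out_dt, 0.02))
        utils::write.csv(cco, out("control_coefficients.csv"),
                         row.names = FALSE)
        cco
      },
      phases = {
        traj <- cc_run_scenario(model, cfg$genotype, list(),
                                horizon = it$horizon, burn_in = it$burn_in,
                                out_dt = it$out_dt)
        sp <- c("Bmal", "Rev", "Ror", "Per", "Cry")
        ph <- data.frame(species = sp, phase_ct = round(peak_phase_ct(traj, sp), 2))
        utils::write.csv(ph, out("phases.csv"), row.names = FALSE)
        ph
      })
  }, error = function(e) e)
  if (inherits(res, "error")) {
    message("numerical failure: ", conditionMessage(res))
    return(invisible(3L))
  }
  cc_save_config(cfg, out("resolved_config.yaml"))
  jsonlite::write_json(
    list(subcommand = sub,
         package_version = as.character(utils::packageVersion("circacycle")),
         seed = cfg$seed,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         schema = "circacycle-summary/1"),
    out("run_info.json"), auto_unbox = TRUE, digits = NA)
  message(sub, " finished; results in ", cfg$output_dir)
  invisible(0L)
}
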