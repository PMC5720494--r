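# Model object, kinetic primitives and right-hand-side access.

#' Hill activation kinetics
#'
#' \code{hill_activation} returns \eqn{x^n / (k^n + x^n)}, the saturating
#' activation factor used for transcriptional activation terms;
#' \code{hill_inhibition} returns the complementary \eqn{k^n / (k^n + x^n)}.
#'
#' @param x non-negative concentration (vectorised).
#' @param k activation/inhibition threshold, must be > 0.
#' @param n Hill exponent, must be > 0.
#' @return Dimensionless factor in [0, 1).
#' @examples
#' hill_activation(2, 1, 4)      # 16/17
#' hill_inhibition(0, 1, 2)      # 1
#' @export
hill_activation <- function(x, k, n) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("hill threshold `k` must be > 0")
  if (any(!is.finite(n)) || any(n <= 0)) stop("hill exponent `n` must be > 0")
  if (any(x < 0, na.rm = TRUE)) stop("concentration `x` must be >= 0")
  xn <- x^n
  xn / (k^n + xn)
}

#' @rdname hill_activation
#' @export
hill_inhibition <- function(x, k, n) {
  1 - hill_activation(x, k, n)
}

# ---------------------------------------------------------------------------
# Model object
# ---------------------------------------------------------------------------

#' Construct a coupled clock/cell-cycle model
#'
#' Builds the model object holding the 170 kinetic parameters, the RAS
#' factor \code{ktt} and the initial state.  With no arguments the packaged
#' calibrated parameter set is used (see \code{\link{cc_load_model}}).
#'
#' @param params named numeric vector of the 170 kinetic parameters (any
#'   order; names must match \code{cc_parameters()}).  \code{NULL} loads the
#'   packaged defaults.
#' @param ktt dimensionless multiplier on CLOCK/BMAL transcriptional
#'   activity; 1 is normal RAS, < 1 RAS overexpression.
#' @param init named numeric vector of initial concentrations (length 46) or
#'   \code{NULL} for the packaged post-burn-in state.
#' @return An object of class \code{cc_model}.
#' @export
cc_model <- function(params = NULL, ktt = 1, init = NULL) {
  base <- cc_load_model()
  if (!is.null(params)) {
    stopifnot(is.numeric(params), !is.null(names(params)))
    if (!setequal(names(params), .CC_PARAMS$name))
      stop("`params` must supply exactly the 170 parameters of cc_parameters()")
    base$params[names(params)] <- params
  }
  if (!is.null(init)) {
    stopifnot(is.numeric(init), !is.null(names(init)))
    if (!setequal(names(init), .CC_SPECIES$name))
      stop("`init` must supply exactly the 46 species of cc_species()")
    base$init[names(init)] <- init
  }
  base$ktt <- ktt
  .cc_validate_model(base)
  base
}

.cc_validate_model <- function(model) {
  stopifnot(inherits(model, "cc_model"))
  p <- model$params
  if (length(p) != .CC_N_PARAMS)
    stop("parameter census violated: expected ", .CC_N_PARAMS,
         " parameters, got ", length(p))
  if (!identical(names(p), .CC_PARAMS$name))
    stop("parameters are not in canonical order")
  if (any(!is.finite(p)) || any(p < 0))
    stop("all kinetic parameters must be finite and >= 0: ",
         paste(names(p)[!is.finite(p) | p < 0], collapse = ", "))
  if (!is.finite(model$ktt) || model$ktt <= 0)
    stop("ktt must be a positive finite number")
  if (length(model$init) != .CC_N_SPECIES)
    stop("species census violated: expected ", .CC_N_SPECIES, " species")
  invisible(TRUE)
}

#' @export
print.cc_model <- function(x, ...) {
  cat("<cc_model> coupled circadian clock / cell-cycle network\n")
  cat("  species:    ", .CC_N_SPECIES, " (", .CC_N_ODE, " ODEs)\n", sep = "")
  cat("  parameters: ", length(x$params), " (+ ktt = ", format(x$ktt), ")\n",
      sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Config I/O
# ---------------------------------------------------------------------------

#' Load a model definition file
#'
#' Reads a structured YAML model definition with blocks \code{species},
#' \code{parameters}, \code{init} and \code{provenance}, validates the
#' species and parameter censuses (46 species, 170 parameters) and returns a
#' \code{cc_model}.  With \code{path = NULL} the packaged calibrated model is
#' loaded.
#'
#' @param path path to a YAML model file, or \code{NULL} for the packaged
#'   default.
#' @return A \code{cc_model}.
#' @export
cc_load_model <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "clockcycle_model.yaml",
                        package = "circacycle", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  for (block in c("species", "parameters", "init"))
    if (is.null(cfg[[block]]))
      stop("model file is missing the `", block, "` block")
  sp <- vapply(cfg$species, function(s) s$name, character(1))
  if (length(sp) != .CC_N_SPECIES || !setequal(sp, .CC_SPECIES$name))
    stop("species census violated in ", path, ": expected the ",
         .CC_N_SPECIES, " species of cc_species()")
  pv <- unlist(cfg$parameters)
  if (length(pv) != .CC_N_PARAMS || !setequal(names(pv), .CC_PARAMS$name))
    stop("parameter census violated in ", path, ": expected the ",
         .CC_N_PARAMS, " parameters of cc_parameters()")
  iv <- unlist(cfg$init)
  if (!setequal(names(iv), .CC_SPECIES$name))
    stop("init block must cover all 46 species")
  model <- structure(list(
    params = pv[.CC_PARAMS$name],
    ktt = 1,
    init = iv[.CC_SPECIES$name],
    provenance = if (is.null(cfg$provenance)) "unspecified" else cfg$provenance
  ), class = "cc_model")
  .cc_validate_model(model)
  model
}

#' Write a model definition file
#'
#' @param model a \code{cc_model}.
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
cc_save_model <- function(model, path) {
  .cc_validate_model(model)
  sp <- .CC_SPECIES
  cfg <- list(
    provenance = model$provenance,
    species = lapply(seq_len(nrow(sp)), function(i)
      list(name = sp$name[i], role = sp$role[i],
           gene_group = sp$gene_group[i], compartment = sp$compartment[i],
           equation = if (is.na(sp$equation[i])) "conserved" else sp$equation[i])),
    parameters = as.list(model$params),
    init = as.list(model$init)
  )
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Right-hand side
# ---------------------------------------------------------------------------

# Assemble the full parameter vector handed to the compiled code:
# 170 kinetic parameters, ktt, knockdown fraction, 46 freeze flags.
.cc_parvec <- function(model, ctx = NULL) {
  if (is.null(ctx)) ctx <- cc_context()
  mask <- as.numeric(ctx$frozen)
  c(model$params, ktt = unname(model$ktt * ctx$ktt), fkd = ctx$kd_bmal, mask)
}

#' Evaluate the model right-hand side
#'
#' Computes the time derivative of every species at state \code{y} under a
#' perturbation context.  Entries of knocked-out or clamped species are 0.
#'
#' @param t time in hours (the system is autonomous; \code{t} is accepted for
#'   interface completeness).
#' @param y named state vector (46 species) or unnamed vector in canonical
#'   order.
#' @param model a \code{cc_model}.
#' @param ctx a perturbation context from \code{\link{cc_context}} (or
#'   \code{NULL} for the unperturbed wild type).
#' @return Named numeric vector of derivatives (1/h), one per species.
#' @export
cc_rhs <- function(t, y, model, ctx = NULL) {
  .cc_validate_model(model)
  if (!is.null(names(y))) {
    if (!setequal(names(y), .CC_SPECIES$name))
      stop("`y` must cover the 46 model species")
    y <- y[.CC_SPECIES$name]
  }
  if (length(y) != .CC_N_SPECIES)
    stop("`y` must have length ", .CC_N_SPECIES)
  bad <- !is.finite(y)
  if (any(bad))
    stop("non-finite state for species: ",
         paste(.CC_SPECIES$name[bad], collapse = ", "))
  out <- .C("cc_rhs_direct", t = as.double(t[1]), y = as.double(y),
            p = as.double(.cc_parvec(model, ctx)),
            ydot = double(.CC_N_SPECIES), PACKAGE = "circacycle")
  setNames(out$ydot, .CC_SPECIES$name)
}
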