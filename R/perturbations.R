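# Intervention algebra: typed, time-stamped perturbations and the static
# context handed to the integrator for each time segment.

.CC_PERTURBATION_KINDS <- c("ras_ktt", "ko_ink4a_arf", "kd_bmal1",
                            "decouple_module1", "decouple_module2",
                            "clamp_species")

#' Create a perturbation specification
#'
#' A perturbation is a typed, time-stamped intervention on the model:
#' \describe{
#'   \item{ras_ktt}{scale CLOCK/BMAL transcriptional activity by
#'     \code{magnitude} (ktt; 1 = normal RAS, < 1 = RAS overexpression,
#'     > 1 = RAS inhibition) from \code{onset} onward.}
#'   \item{ko_ink4a_arf}{double knockout of the Ink4a/Arf locus: the six
#'     INK4a/ARF species (mRNAs, cytoplasmic and nuclear proteins; rate
#'     equations 1, 2, 8, 10, 14, 19) and their rates of change are set
#'     to 0.}
#'   \item{kd_bmal1}{knockdown: Bmal transcription scaled by
#'     \code{magnitude} (residual fraction in (0, 1]).}
#'   \item{decouple_module1}{sever the INK4a/RB1/E2F1 pathway from the clock
#'     by forcing the E2F species to 0 (equations 7, 12, 22).}
#'   \item{decouple_module2}{sever the ARF/MDM2/p53 pathway by forcing
#'     p53_N to 0 (equation 16).}
#'   \item{clamp_species}{hold species \code{target} constant at
#'     \code{magnitude} from \code{onset}; its derivative is 0.}
#' }
#'
#' @param kind one of the kinds above.
#' @param onset time (hours, >= 0) at which the perturbation switches on.
#' @param magnitude ktt value, knockdown fraction, or clamp level.
#' @param target species name (clamp_species only).
#' @return A \code{cc_perturbation} object.
#' @export
cc_perturbation <- function(kind, onset = 0, magnitude = NULL, target = NULL) {
  kind <- match.arg(kind, .CC_PERTURBATION_KINDS)
  if (!is.numeric(onset) || length(onset) != 1 || !is.finite(onset) || onset < 0)
    stop("`onset` must be a single non-negative time in hours")
  spec <- structure(list(kind = kind, onset = onset, magnitude = magnitude,
                         target = target), class = "cc_perturbation")
  switch(kind,
    ras_ktt = {
      if (is.null(magnitude) || !is.finite(magnitude) || magnitude <= 0)
        stop("ras_ktt requires magnitude (ktt) > 0")
    },
    kd_bmal1 = {
      if (is.null(magnitude)) spec$magnitude <- 0.3
      else if (!is.finite(magnitude) || magnitude <= 0 || magnitude > 1)
        stop("kd_bmal1 requires a residual fraction in (0, 1]")
    },
    clamp_species = {
      if (is.null(target) || !target %in% .CC_SPECIES$name)
        stop("clamp_species requires `target`, one of the 46 model species")
      if (is.null(magnitude) || !is.finite(magnitude) || magnitude < 0)
        stop("clamp_species requires a clamp level >= 0")
    },
    ko_ink4a_arf = , decouple_module1 = , decouple_module2 = {
      spec$magnitude <- NULL
    })
  spec
}

#' @export
print.cc_perturbation <- function(x, ...) {
  cat("<cc_perturbation>", x$kind,
      if (!is.null(x$target)) paste0("[", x$target, "]"),
      if (!is.null(x$magnitude)) paste0("= ", format(x$magnitude)),
      "@", x$onset, "h\n")
  invisible(x)
}

#' Convenience constructors for the study's interventions
#'
#' Thin wrappers over \code{\link{cc_perturbation}} for the interventions
#' used throughout: RAS activity scaling, Ink4a/Arf double knockout, Bmal1
#' knockdown, module decoupling and species clamping.
#'
#' @param ktt,fraction,level magnitudes (see \code{\link{cc_perturbation}}).
#' @param onset onset time in hours.
#' @param target species to clamp.
#' @name interventions
#' @export
apply_ras <- function(ktt, onset = 0)
  cc_perturbation("ras_ktt", onset = onset, magnitude = ktt)

#' @rdname interventions
#' @export
knockout_ink4a_arf <- function(onset = 0)
  cc_perturbation("ko_ink4a_arf", onset = onset)

#' @rdname interventions
#' @export
knockdown_bmal1 <- function(fraction = 0.3, onset = 0)
  cc_perturbation("kd_bmal1", onset = onset, magnitude = fraction)

#' @rdname interventions
#' @export
decouple_module1 <- function(onset = 0)
  cc_perturbation("decouple_module1", onset = onset)

#' @rdname interventions
#' @export
decouple_module2 <- function(onset = 0)
  cc_perturbation("decouple_module2", onset = onset)

#' @rdname interventions
#' @export
clamp_species <- function(target, level, onset = 0)
  cc_perturbation("clamp_species", onset = onset, magnitude = level,
                  target = target)

# ---------------------------------------------------------------------------
# Perturbation context: the static modification of the vector field that is
# in force during one integration segment.
# ---------------------------------------------------------------------------

#' Build a static perturbation context
#'
#' The context collects every modification of the vector field that is
#' active during one integration segment: the effective ktt, the Bmal1
#' knockdown fraction, and the set of frozen species (knockouts and clamps)
#' with their enforced values.
#'
#' @param ktt RAS factor (> 0), default 1.
#' @param kd_bmal residual Bmal transcription fraction in (0, 1], default 1.
#' @param frozen character vector of species held constant.
#' @param values named numeric vector of enforced state values for (a subset
#'   of) the frozen species; frozen species without a value keep their state
#'   at segment start.
#' @return A \code{cc_context}.
#' @export
cc_context <- function(ktt = 1, kd_bmal = 1, frozen = character(),
                       values = numeric()) {
  stopifnot(is.finite(ktt), ktt > 0, is.finite(kd_bmal),
            kd_bmal > 0, kd_bmal <= 1)
  if (!all(frozen %in% .CC_SPECIES$name))
    stop("unknown species in `frozen`: ",
         paste(setdiff(frozen, .CC_SPECIES$name), collapse = ", "))
  if (length(values) && !all(names(values) %in% frozen))
    stop("`values` may only name frozen species")
  structure(list(
    ktt = ktt, kd_bmal = kd_bmal,
    frozen = setNames(.CC_SPECIES$name %in% frozen, .CC_SPECIES$name),
    values = values
  ), class = "cc_context")
}

# Fold a list of perturbation specs that are active (onset already passed)
# into one static context.  Idempotent: applying a spec twice equals once.
.cc_fold_context <- function(specs) {
  ktt <- 1; fkd <- 1
  frozen <- character(); values <- numeric()
  for (s in specs) {
    stopifnot(inherits(s, "cc_perturbation"))
    switch(s$kind,
      ras_ktt = { ktt <- s$magnitude },
      kd_bmal1 = { fkd <- s$magnitude },
      ko_ink4a_arf = {
        frozen <- union(frozen, .CC_KO_SPECIES)
        values[.CC_KO_SPECIES] <- 0
      },
      decouple_module1 = {
        frozen <- union(frozen, .CC_M1_SPECIES)
        values[.CC_M1_SPECIES] <- 0
      },
      decouple_module2 = {
        frozen <- union(frozen, .CC_M2_SPECIES)
        values[.CC_M2_SPECIES] <- 0
      },
      clamp_species = {
        frozen <- union(frozen, s$target)
        values[s$target] <- s$magnitude
      })
  }
  cc_context(ktt = ktt, kd_bmal = fkd, frozen = frozen, values = values)
}
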