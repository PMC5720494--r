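#' @useDynLib circacycle, .registration = TRUE
#' @importFrom stats lm coef optim setNames aggregate approx
#' @importFrom utils head tail write.table modifyList
NULL

# ---------------------------------------------------------------------------
# Species census.
#
# 46 species, 45 ODEs.  Cell-cycle equations come first (1-26), clock
# equations second (27-45).  RB1p_N carries no ODE: the RB1 pool is conserved
# (RB1_N + RBE2F + RB1p_N = rb_tot), so the phosphorylated form is computed
# algebraically and reported as the 46th variable.
#
# The equation index of each dynamic species is fixed by design so that the
# published knockout/decoupling recipes are executable by index:
#   Ink4a/Arf knockout ......... equations 1, 2, 8, 10, 14, 19 = 0
#   module-1 decoupling (E2F) .. equations 7, 12, 22 = 0
#   module-2 decoupling (p53) .. equation 16 = 0
# ---------------------------------------------------------------------------

.cc_species_table <- function() {
  df <- data.frame(
    name = c(
      # cell cycle: mRNAs (eq 1-7)
      "Ink4a", "Arf", "Myc", "Wee1", "Mdm2", "p53", "E2f",
      # cell cycle: cytoplasmic proteins (eq 8-13)
      "INK4A_C", "MYC_C", "ARF_C", "MDM2_C", "E2F_C", "WEE1_C",
      # cell cycle: nuclear proteins and complexes (eq 14-26)
      "INK4A_N", "MYC_N", "p53_N", "MDM2_N", "WEE1_N", "ARF_N",
      "RB1_N", "RBE2F", "E2F_N", "Cdc", "CDC_C", "CDC_N", "CDCI",
      # conserved phosphorylated RB1 (no ODE)
      "RB1p_N",
      # clock: mRNAs (eq 27-31)
      "Bmal", "Per", "Cry", "Rev", "Ror",
      # clock: cytoplasmic proteins (eq 32-36)
      "BMAL_C", "PER_C", "CRY_C", "REV_C", "ROR_C",
      # clock: nuclear proteins (eq 37-41)
      "BMAL_N", "PER_N", "CRY_N", "REV_N", "ROR_N",
      # clock: complexes (eq 42-45)
      "PERCRY_C", "PERCRY_N", "CB", "CBI"
    ),
    role = c(
      rep("mRNA", 7),
      rep("protein_cytoplasm", 6),
      rep("protein_nucleus", 6),
      "protein_nucleus", "complex", "protein_nucleus",
      "mRNA", "protein_cytoplasm", "protein_nucleus", "complex",
      "protein_nucleus",
      rep("mRNA", 5),
      rep("protein_cytoplasm", 5),
      rep("protein_nucleus", 5),
      "complex", "complex", "complex", "complex"
    ),
    gene_group = c(
      "Ink4a", "Arf", "Myc", "Wee1", "Mdm2", "p53", "E2f",
      "Ink4a", "Myc", "Arf", "Mdm2", "E2f", "Wee1",
      "Ink4a", "Myc", "p53", "Mdm2", "Wee1", "Arf",
      "Rb1", "Rb1", "E2f", "CdkCyc", "CdkCyc", "CdkCyc", "CdkCyc",
      "Rb1",
      "Bmal", "Per", "Cry", "Rev-Erb", "Ror",
      "Bmal", "Per", "Cry", "Rev-Erb", "Ror",
      "Bmal", "Per", "Cry", "Rev-Erb", "Ror",
      "Clock-related complex", "Clock-related complex",
      "Clock-related complex", "Clock-related complex"
    ),
    compartment = c(
      rep("cytoplasm", 13),
      rep("nucleus", 13),
      "nucleus",
      rep("cytoplasm", 10),
      rep("nucleus", 5),
      "cytoplasm", "nucleus", "nucleus", "nucleus"
    ),
    stringsAsFactors = FALSE
  )
  # equation index: NA for the conserved species
  eq <- rep(NA_integer_, nrow(df))
  dyn <- df$name != "RB1p_N"
  eq[dyn] <- seq_len(sum(dyn))
  df$equation <- eq
  df
}

.CC_SPECIES <- .cc_species_table()
.CC_N_SPECIES <- nrow(.CC_SPECIES)            # 46
.CC_N_ODE <- sum(!is.na(.CC_SPECIES$equation)) # 45

# The six species zeroed by the Ink4a/Arf knockout and the modules' species.
.CC_KO_SPECIES <- c("Ink4a", "Arf", "INK4A_C", "ARF_C", "INK4A_N", "ARF_N")
.CC_M1_SPECIES <- c("E2f", "E2F_C", "E2F_N")
.CC_M2_SPECIES <- "p53_N"

# ---------------------------------------------------------------------------
# Parameter census: 170 kinetic parameters (+ the dimensionless RAS factor
# ktt, handled separately).  `time_unit` flags parameters whose units carry
# 1/h (rescaled by the uniform time-rescaling operation); thresholds (conc),
# Hill exponents and pool sizes are left untouched by rescaling.
# ---------------------------------------------------------------------------

.cc_parameter_table <- function() {
  p <- function(name, time_unit) data.frame(name = name, time_unit = time_unit,
                                            stringsAsFactors = FALSE)
  tr <- function(gene, src) {
    # transcription block: basal + regulated Vmax + threshold + exponent
    #                      + Michaelis constant and Vmax of mRNA decay
    rbind(p(paste0("vb_", gene), TRUE), p(paste0("v_", gene), TRUE),
          p(paste0("ka_", gene, "_", src), FALSE),
          p(paste0("ha_", gene, "_", src), FALSE),
          p(paste0("km_", gene), FALSE), p(paste0("dm_", gene), TRUE))
  }
  prot <- function(tag) rbind(p(paste0("kt_", tag), TRUE),
                              p(paste0("ki_", tag), TRUE),
                              p(paste0("dc_", tag), TRUE))
  tab <- rbind(
    # --- cell-cycle transcription -------------------------------------
    tr("ink", "pc"),          # Ink4a  <- PER/CRY_N (activation)
    tr("arf", "myc"),         # Arf    <- MYC_N (activation)
    p("vb_myc", TRUE), p("v_myc", TRUE), p("ki_myc_cb", FALSE),
    p("hi_myc_cb", FALSE), p("km_myc", FALSE), p("dm_myc", TRUE),
    tr("wee1", "cb"),         # Wee1   <- CLOCK/BMAL (activation)
    tr("mdm2", "p53"),        # Mdm2   <- p53_N (activation)
    p("vb_p53", TRUE), p("km_p53", FALSE), p("dm_p53", TRUE),
    p("vb_e2f", TRUE), p("v_e2f", TRUE), p("ka_e2f_myc", FALSE),
    p("ha_e2f_myc", FALSE),
    p("v_e2f_auto", TRUE), p("ka_e2f_auto", FALSE), p("ha_e2f_auto", FALSE),
    p("km_e2f", FALSE), p("dm_e2f", TRUE),
    tr("cdc", "e2f"),         # CycD/CDK pool mRNA <- E2F_N
    # --- cell-cycle translation / import / cytoplasmic decay ----------
    prot("ink4a"), prot("myc"), prot("arf"), prot("mdm2"),
    prot("e2f"), prot("wee1"), prot("cdc"),
    # --- cell-cycle nuclear steps -------------------------------------
    p("dn_ink4a", TRUE), p("kf_ick", TRUE), p("kd_ick", TRUE),
    p("dn_myc", TRUE),
    p("kt_p53", TRUE), p("d_p53", TRUE),
    p("v_dp53_mdm2", FALSE), p("kd_p53_mdm2", FALSE), p("hd_p53_mdm2", FALSE),
    p("dn_mdm2", TRUE),
    p("v_dmdm2_arf", FALSE), p("kd_mdm2_arf", FALSE), p("hd_mdm2_arf", FALSE),
    p("dn_wee1", TRUE), p("dn_arf", TRUE),
    p("rb_tot", FALSE), p("k_phos", TRUE), p("km_phos", FALSE),
    p("k_dephos", TRUE), p("ki_rbp_p53", FALSE), p("hi_rbp_p53", FALSE),
    p("kf_re", TRUE), p("kd_re", TRUE), p("k_phos2", TRUE),
    p("dn_e2f", TRUE), p("dn_cdc", TRUE), p("d_cdci", TRUE),
    # --- MYC interference with E-box transcription --------------------
    p("ki_ebox_myc", FALSE), p("hi_ebox_myc", FALSE),
    # --- clock transcription ------------------------------------------
    p("vb_bmal", TRUE), p("v_bmal", TRUE),
    p("ka_bmal_ror", FALSE), p("ha_bmal_ror", FALSE),
    p("ki_bmal_rev", FALSE), p("hi_bmal_rev", FALSE),
    p("v_bmal_e2f", TRUE), p("ka_bmal_e2f", FALSE), p("ha_bmal_e2f", FALSE),
    p("km_bmal", FALSE), p("dm_bmal", TRUE),
    p("vb_per", TRUE), p("v_per", TRUE), p("ka_per_cb", FALSE),
    p("ha_per_cb", FALSE), p("ki_per_p53", FALSE), p("hi_per_p53", FALSE),
    p("km_per", FALSE), p("dm_per", TRUE),
    p("vb_cry", TRUE), p("v_cry", TRUE), p("ka_cry_cb", FALSE),
    p("ha_cry_cb", FALSE), p("ki_cry_rev", FALSE), p("hi_cry_rev", FALSE),
    p("km_cry", FALSE), p("dm_cry", TRUE),
    p("vb_rev", TRUE), p("v_rev", TRUE), p("ka_rev_cb", FALSE),
    p("ha_rev_cb", FALSE), p("km_rev", FALSE), p("dm_rev", TRUE),
    p("vb_ror", TRUE), p("v_ror", TRUE), p("ka_ror_cb", FALSE),
    p("ha_ror_cb", FALSE), p("km_ror", FALSE), p("dm_ror", TRUE),
    # --- clock translation / import / cytoplasmic decay ---------------
    prot("bmal"), prot("per"), prot("cry"), prot("rev"), prot("ror"),
    p("dn_bmal", TRUE), p("k_cbform", TRUE),
    p("dn_per", TRUE), p("dn_cry", TRUE), p("dn_rev", TRUE), p("dn_ror", TRUE),
    # --- clock complexes ----------------------------------------------
    p("kf_pc", TRUE), p("kd_pc", TRUE), p("ki_pc", TRUE), p("dc_percry", TRUE),
    p("kf_pcn", TRUE), p("kd_pcn", TRUE), p("ke_pc", TRUE), p("dn_percry", TRUE),
    p("kf_cbi", TRUE), p("kd_cbi", TRUE), p("d_cb", TRUE), p("d_cbi", TRUE)
  )
  rownames(tab) <- NULL
  tab
}

.CC_PARAMS <- .cc_parameter_table()
.CC_N_PARAMS <- nrow(.CC_PARAMS)  # 170

#' Species census of the coupled clock/cell-cycle model
#'
#' Returns the full species table of the network: 46 species spanning the
#' circadian core-clock (Bmal, Per, Cry, Rev-Erb, Ror, the active CLOCK/BMAL
#' complex CB, the inactivated CLOCK/BMAL:PER/CRY complex CBI and the PER/CRY
#' complexes) and the cell-cycle arm (Ink4a, Arf, Myc, Wee1, Mdm2, p53, E2f,
#' Rb1 and the CDK/cyclin pool).  For most gene entities the mRNA,
#' cytoplasmic protein and nuclear protein are distinguished.
#'
#' @return A data frame with columns \code{name}, \code{role} (one of
#'   \code{mRNA}, \code{protein_cytoplasm}, \code{protein_nucleus},
#'   \code{complex}), \code{gene_group}, \code{compartment} and
#'   \code{equation} (the index of the species' rate equation; \code{NA} for
#'   the conserved phosphorylated RB1 pool, which is the 46th variable of the
#'   45-ODE system).
#' @export
cc_species <- function() .CC_SPECIES

#' Parameter census of the model
#'
#' @return A data frame with the 170 kinetic parameter names and a logical
#'   \code{time_unit} column flagging parameters whose units carry 1/h (these
#'   are the ones affected by uniform time rescaling).  The RAS factor
#'   \code{ktt} is not part of this census; it is a dimensionless multiplier
#'   handled by the perturbation layer.
#' @export
cc_parameters <- function() .CC_PARAMS

#' Map published equation indices to species names
#'
#' The model's rate equations are numbered 1-45 (cell cycle first, clock
#' second); intervention recipes given as equation indices (e.g. the
#' Ink4a/Arf knockout "equations 1, 2, 8, 10, 14, 19 = 0") can be translated
#' to species with this map.
#'
#' @param eq integer vector of equation indices (1-45).
#' @return Character vector of species names.
#' @export
cc_equation_species <- function(eq) {
  stopifnot(all(eq %in% seq_len(.CC_N_ODE)))
  sp <- .CC_SPECIES[!is.na(.CC_SPECIES$equation), ]
  sp$name[match(eq, sp$equation)]
}

# ---------------------------------------------------------------------------
# Interaction wiring (for introspection and edge-list export).
# ---------------------------------------------------------------------------

.cc_interaction_table <- function() {
  e <- function(src, tgt, sign, mech, ktt = FALSE)
    data.frame(source = src, target = tgt, sign = sign, mechanism = mech,
               ktt_scaled = ktt, stringsAsFactors = FALSE)
  rbind(
    # E-box transcription driven by the active CLOCK/BMAL complex (ktt-scaled)
    e("CB", "Per",  "activation", "hill_activation", TRUE),
    e("CB", "Cry",  "activation", "hill_activation", TRUE),
    e("CB", "Rev",  "activation", "hill_activation", TRUE),
    e("CB", "Ror",  "activation", "hill_activation", TRUE),
    e("CB", "Wee1", "activation", "hill_activation", TRUE),
    e("CB", "Myc",  "inhibition", "hill_inhibition", TRUE),
    # MYC competitive E-box interference with CLOCK/BMAL-driven transcription
    e("MYC_N", "CB", "inhibition", "hill_inhibition"),
    # RORE regulation of Bmal and the predicted E2F->Bmal activation
    e("ROR_N", "Bmal", "activation", "hill_activation"),
    e("REV_N", "Bmal", "inhibition", "hill_inhibition"),
    e("E2F_N", "Bmal", "activation", "hill_activation"),
    # clock protein processing
    e("Bmal", "BMAL_C", "activation", "mass_action"),
    e("BMAL_C", "BMAL_N", "activation", "mass_action"),
    e("BMAL_N", "CB", "activation", "mass_action"),
    e("Per", "PER_C", "activation", "mass_action"),
    e("Cry", "CRY_C", "activation", "mass_action"),
    e("Rev", "REV_C", "activation", "mass_action"),
    e("Ror", "ROR_C", "activation", "mass_action"),
    e("PER_C", "PER_N", "activation", "mass_action"),
    e("CRY_C", "CRY_N", "activation", "mass_action"),
    e("REV_C", "REV_N", "activation", "mass_action"),
    e("ROR_C", "ROR_N", "activation", "mass_action"),
    e("PER_C", "PERCRY_C", "activation", "complex_formation"),
    e("CRY_C", "PERCRY_C", "activation", "complex_formation"),
    e("PER_N", "PERCRY_N", "activation", "complex_formation"),
    e("CRY_N", "PERCRY_N", "activation", "complex_formation"),
    e("PERCRY_C", "PERCRY_N", "activation", "mass_action"),
    e("PERCRY_N", "CBI", "activation", "complex_formation"),
    e("CB", "CBI", "activation", "complex_formation"),
    # module 1: INK4a/RB1/E2F1
    e("PERCRY_N", "Ink4a", "activation", "hill_activation"),
    e("Ink4a", "INK4A_C", "activation", "mass_action"),
    e("INK4A_C", "INK4A_N", "activation", "mass_action"),
    e("INK4A_N", "CDC_N", "inhibition", "complex_formation"),
    e("CDC_N", "RB1_N", "inhibition", "michaelis_menten"),   # phosphorylation
    e("RB1_N", "E2F_N", "inhibition", "complex_formation"),
    e("E2F_N", "Cdc", "activation", "hill_activation"),
    e("E2F_N", "E2f", "activation", "hill_activation"),
    e("Myc", "MYC_C", "activation", "mass_action"),
    e("MYC_C", "MYC_N", "activation", "mass_action"),
    e("MYC_N", "Arf", "activation", "hill_activation"),
    e("MYC_N", "E2f", "activation", "hill_activation"),
    e("E2f", "E2F_C", "activation", "mass_action"),
    e("E2F_C", "E2F_N", "activation", "mass_action"),
    e("Cdc", "CDC_C", "activation", "mass_action"),
    e("CDC_C", "CDC_N", "activation", "mass_action"),
    e("Wee1", "WEE1_C", "activation", "mass_action"),
    e("WEE1_C", "WEE1_N", "activation", "mass_action"),
    # module 2: ARF/MDM2/p53
    e("Arf", "ARF_C", "activation", "mass_action"),
    e("ARF_C", "ARF_N", "activation", "mass_action"),
    e("ARF_N", "MDM2_N", "inhibition", "hill_inhibition"),   # degradation
    e("MDM2_N", "p53_N", "inhibition", "hill_inhibition"),   # degradation
    e("p53", "p53_N", "activation", "mass_action"),
    e("p53_N", "Mdm2", "activation", "hill_activation"),
    e("p53_N", "Per", "inhibition", "hill_inhibition"),
    e("p53_N", "RB1_N", "activation", "hill_inhibition"),    # blocks phosphorylation
    e("Mdm2", "MDM2_C", "activation", "mass_action"),
    e("MDM2_C", "MDM2_N", "activation", "mass_action")
  )
}

.CC_INTERACTIONS <- .cc_interaction_table()

#' Interaction wiring of the model
#'
#' @return A data frame of directed interactions (\code{source},
#'   \code{target}, \code{sign}, \code{mechanism}, \code{ktt_scaled}).  The
#'   \code{ktt_scaled} column marks the CLOCK/BMAL-mediated transcription
#'   terms whose effective transactivator activity is multiplied by the RAS
#'   factor ktt.
#' @export
cc_interactions <- function() .CC_INTERACTIONS

#' Export the reaction network as an edge-list TSV
#'
#' @param path output file path.
#' @return The path, invisibly.
#' @export
cc_write_edgelist <- function(path) {
  write.table(.CC_INTERACTIONS, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
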