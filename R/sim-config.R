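#' Reference coordinates of edited elements
#'
#' Each CRISPR-targeted locus is genotyped on the reference frame of its
#' unedited PCR amplicon. Coordinates are 0-based, half-open. `element_start`
#' and `element_end` delimit the functional element whose disruption is
#' scored (for the HBG1/2 promoters, the 13 bp BCL11A-binding element at
#' positions -101 to -114 relative to the TSS, placed at `[100, 113)` on the
#' amplicon frame); `cut_site` is the nominal Cas9 cut position used by the
#' simulator.
#'
#' @return A data.frame with columns `locus`, `amplicon_length`,
#'   `element_start`, `element_end`, `cut_site`.
#' @export
element_coords <- function() {
  data.frame(
    locus = c("HBG1_prom", "HBG2_prom", "BCL11A_e2", "BCL11A_e4",
              "ZBTB7A", "AAVS1"),
    amplicon_length = c(240L, 240L, 200L, 200L, 200L, 200L),
    element_start = c(100L, 100L, 80L, 80L, 80L, 80L),
    element_end   = c(113L, 113L, 120L, 120L, 120L, 120L),
    cut_site      = c(107L, 107L, 100L, 100L, 100L, 100L),
    stringsAsFactors = FALSE
  )
}

# structural elements assayed by junction qPCR rather than amplicon sequencing
.structural_elements <- c("hbb_hbd", "hbd_3p5kb", "hbb_3p5kb")

# guide -> locus map used by the simulator
.single_cut_guides <- c(HBG13 = "HBG_prom", BCL11A_e2 = "BCL11A_e2",
                        BCL11A_e4 = "BCL11A_e4", ZBTB7A = "ZBTB7A",
                        AAVS1 = "AAVS1")
.paired_guides <- c(HBB_HBD = "hbb_hbd", HBD_3p5kb = "hbd_3p5kb",
                    HBB_3p5kb = "hbb_3p5kb")

#' Simulation configuration for a synthetic colony study
#'
#' Defines the experimental arms and per-allele editing outcome
#' probabilities for [simulate_colonies()]. Each condition is a set of
#' guides delivered together; single-cut guides (`"HBG13"`, `"BCL11A_e2"`,
#' `"BCL11A_e4"`, `"ZBTB7A"`, `"AAVS1"`) produce indels at their locus with
#' probability `per_guide_edit_prob` per allele, with signed indel lengths
#' drawn from `indel_spectrum`; paired-guide elements (`"HBB_HBD"`,
#' `"HBD_3p5kb"`, `"HBB_3p5kb"`) produce per-allele deletions or inversions
#' of the flanked element. The `"HBG13"` guide targets the homologous 13 bp
#' element in both HBG1 and HBG2 promoters, so all four promoter alleles
#' are at risk independently.
#'
#' @param donors Number of cell donors; colonies are spread evenly over
#'   donors within each condition.
#' @param colonies_per_condition Colonies per condition (per all donors).
#' @param conditions Named list; each element a character vector of guide
#'   names delivered in that arm. Defaults to the arms of the study design:
#'   an AAVS1 control, single perturbations, and pairwise combinations.
#' @param per_guide_edit_prob Probability that an allele at a single-cut
#'   guide's locus acquires an edit (independent per allele).
#' @param indel_spectrum Named numeric vector of probabilities over signed
#'   indel lengths (names such as `"-13"`, `"+1"`); must sum to 1.
#' @param paired_deletion_prob,paired_inversion_prob Per-allele probability
#'   that a paired-guide element is deleted, resp. inverted; their sum must
#'   not exceed 1 (remainder stays intact).
#' @param whole_region_del_prob Per-colony probability of a whole
#'   HBG1-to-HBB region deletion artifact when three or more guides target
#'   the beta-globin locus simultaneously; such colonies are flagged for
#'   exclusion.
#' @param seed Integer random seed stored with the configuration.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(donors = 3L,
                       colonies_per_condition = 30L,
                       conditions = default_conditions(),
                       per_guide_edit_prob = 0.7,
                       indel_spectrum = c("-13" = 0.50, "-7" = 0.10,
                                          "-2" = 0.10, "-1" = 0.15,
                                          "+1" = 0.15),
                       paired_deletion_prob = 0.35,
                       paired_inversion_prob = 0.10,
                       whole_region_del_prob = 0.8,
                       seed = 1L) {
  stopifnot(donors >= 1, colonies_per_condition >= 1)
  if (!is.list(conditions) || is.null(names(conditions)) ||
      any(names(conditions) == ""))
    stop("`conditions` must be a named list of guide sets", call. = FALSE)
  known <- c(names(.single_cut_guides), names(.paired_guides))
  bad <- setdiff(unlist(conditions), known)
  if (length(bad))
    stop("unknown guide(s): ", paste(bad, collapse = ", "), call. = FALSE)
  .check_prob(per_guide_edit_prob, "per_guide_edit_prob")
  .check_prob(paired_deletion_prob, "paired_deletion_prob")
  .check_prob(paired_inversion_prob, "paired_inversion_prob")
  .check_prob(whole_region_del_prob, "whole_region_del_prob")
  if (paired_deletion_prob + paired_inversion_prob > 1)
    stop("paired_deletion_prob + paired_inversion_prob must be <= 1",
         call. = FALSE)
  if (!is.numeric(indel_spectrum) || is.null(names(indel_spectrum)))
    stop("`indel_spectrum` must be a named numeric vector", call. = FALSE)
  if (any(indel_spectrum < 0) || abs(sum(indel_spectrum) - 1) > 1e-8)
    stop("indel_spectrum probabilities must be non-negative and sum to 1",
         call. = FALSE)
  lens <- suppressWarnings(as.integer(names(indel_spectrum)))
  if (anyNA(lens) || any(lens == 0))
    stop("indel_spectrum names must be non-zero signed integers",
         call. = FALSE)
  structure(list(
    donors = as.integer(donors),
    colonies_per_condition = as.integer(colonies_per_condition),
    conditions = conditions,
    per_guide_edit_prob = per_guide_edit_prob,
    indel_spectrum = indel_spectrum,
    paired_deletion_prob = paired_deletion_prob,
    paired_inversion_prob = paired_inversion_prob,
    whole_region_del_prob = whole_region_del_prob,
    seed = as.integer(seed)
  ), class = "sim_config")
}

.check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("`", name, "` must be a probability in [0, 1]", call. = FALSE)
}

#' Default experimental arms
#'
#' The arms mirror the study design: an AAVS1 safe-harbor control, single
#' perturbations of each cis element and trans factor, and the pairwise
#' combinations interrogated by the three interaction models (partial
#' deletions together; BCL11A with the HBG1/2 promoter element and with the
#' HBB-3.5kb element; ZBTB7A with the HBB-3.5kb element and with BCL11A).
#'
#' @return Named list of guide-name character vectors.
#' @export
default_conditions <- function() {
  list(
    AAVS1          = "AAVS1",
    HBG13          = "HBG13",
    BCL11A_e2      = "BCL11A_e2",
    BCL11A_e4      = "BCL11A_e4",
    ZBTB7A         = "ZBTB7A",
    HBB_HBD        = "HBB_HBD",
    HBD_3p5kb      = "HBD_3p5kb",
    HBB_HBD_x_HBD  = c("HBB_HBD", "HBD_3p5kb"),
    HBB_3p5kb      = "HBB_3p5kb",
    HBG13_Be2      = c("HBG13", "BCL11A_e2"),
    HBG13_Be4      = c("HBG13", "BCL11A_e4"),
    HBB35_Be2      = c("HBB_3p5kb", "BCL11A_e2"),
    HBB35_Be4      = c("HBB_3p5kb", "BCL11A_e4"),
    HBB35_ZB       = c("HBB_3p5kb", "ZBTB7A"),
    Be2_ZB         = c("BCL11A_e2", "ZBTB7A")
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic colony study configuration\n")
  cat("  donors:", x$donors,
      " colonies/condition:", x$colonies_per_condition,
      " conditions:", length(x$conditions), "\n")
  cat("  per-allele edit probability:", x$per_guide_edit_prob, "\n")
  cat("  indel spectrum:",
      paste(sprintf("%s:%.2f", names(x$indel_spectrum), x$indel_spectrum),
            collapse = " "), "\n")
  cat("  paired deletion/inversion prob:", x$paired_deletion_prob, "/",
      x$paired_inversion_prob, "\n")
  invisible(x)
}

#' Genotype-to-expression architecture for the simulator
#'
#' Specifies how dosage-coded genotypes generate globin expression:
#' the HBG1/2 fraction of beta-like mRNA in an unedited colony
#' (`baseline_hbg_fraction`), additive per-dosage-unit fixed effects,
#' pairwise dosage-by-dosage interaction effects, and donor / guide-set
#' random intercepts plus residual noise. On the default `"identity"`
#' scale the response is the HBG fraction (0-1) and predictions are
#' clipped to that range; on the `"log"` scale effects act on
#' log(HBG fraction).
#'
#' @param baseline_hbg_fraction Expected HBG1/2 fraction of beta-like mRNA
#'   in unedited colonies, in (0, 1).
#' @param main_effects Named numeric vector: effect per dosage unit on the
#'   response scale, names among the dosage variables
#'   (`hbg_dosage`, `bcl11a_series`, `bcl11a_e2_dosage`, `zbtb7a_dosage`,
#'   `hbb_hbd`, `hbd_3p5kb`, `hbb_3p5kb`).
#' @param interaction_effects Named numeric vector with names of the form
#'   `"a:b"` joining two dosage variables.
#' @param donor_sd,guide_sd Standard deviations of donor and guide-set
#'   random intercepts (response scale), >= 0.
#' @param residual_sd Residual standard deviation, >= 0.
#' @param response_scale `"identity"` or `"log"`.
#' @return An object of class `"phenotype_model"`.
#' @export
phenotype_model <- function(baseline_hbg_fraction = 0.20,
                            main_effects = c(hbg_dosage = 0.10,
                                             bcl11a_series = 0.12,
                                             zbtb7a_dosage = 0.15,
                                             hbb_hbd = 0.12,
                                             hbd_3p5kb = 0.08,
                                             hbb_3p5kb = 0.15),
                            interaction_effects =
                              c("hbb_hbd:hbd_3p5kb" = 0.05,
                                "hbg_dosage:bcl11a_series" = -0.03,
                                "hbb_3p5kb:bcl11a_series" = -0.04,
                                "hbb_3p5kb:zbtb7a_dosage" = -0.07,
                                "bcl11a_series:zbtb7a_dosage" = 0),
                            donor_sd = 0.03,
                            guide_sd = 0.03,
                            residual_sd = 0.08,
                            response_scale = c("identity", "log")) {
  response_scale <- match.arg(response_scale)
  if (!is.numeric(baseline_hbg_fraction) ||
      baseline_hbg_fraction <= 0 || baseline_hbg_fraction >= 1)
    stop("`baseline_hbg_fraction` must lie in (0, 1)", call. = FALSE)
  if (length(main_effects) && is.null(names(main_effects)))
    stop("`main_effects` must be named", call. = FALSE)
  if (length(interaction_effects)) {
    if (is.null(names(interaction_effects)))
      stop("`interaction_effects` must be named", call. = FALSE)
    pair_ok <- vapply(strsplit(names(interaction_effects), ":", fixed = TRUE),
                      length, 1L) == 2L
    if (!all(pair_ok))
      stop("interaction effect names must be of the form \"a:b\"",
           call. = FALSE)
  }
  if (donor_sd < 0 || guide_sd < 0 || residual_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(list(
    baseline_hbg_fraction = baseline_hbg_fraction,
    main_effects = main_effects,
    interaction_effects = interaction_effects,
    donor_sd = donor_sd, guide_sd = guide_sd, residual_sd = residual_sd,
    response_scale = response_scale
  ), class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("Phenotype model (", x$response_scale, " scale)\n", sep = "")
  cat("  baseline HBG fraction:", x$baseline_hbg_fraction, "\n")
  cat("  main effects:\n")
  for (nm in names(x$main_effects))
    cat(sprintf("    %-28s %+.3f\n", nm, x$main_effects[[nm]]))
  if (length(x$interaction_effects)) {
    cat("  interaction effects:\n")
    for (nm in names(x$interaction_effects))
      cat(sprintf("    %-28s %+.3f\n", nm, x$interaction_effects[[nm]]))
  }
  cat(sprintf("  sd: donor %.3f, guide %.3f, residual %.3f\n",
              x$donor_sd, x$guide_sd, x$residual_sd))
  invisible(x)
}
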