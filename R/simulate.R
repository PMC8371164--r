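#' Simulate genotypes for a synthetic colony study
#'
#' Draws per-allele CRISPR editing outcomes for every colony in every
#' condition of a [sim_config()]. Single-cut loci receive indels with the
#' configured per-allele probability and indel-length spectrum; paired-guide
#' structural elements receive per-allele deletions or inversions. Each
#' colony carries four HBG promoter alleles (two per homologous promoter)
#' and two alleles at every other locus, all edited independently.
#'
#' The return value bundles the generative truth (`colonies`: one row per
#' colony with all dosage codes, structural-variant flags and exclusion
#' status), the allele-level edit records (`alleles`) from which the
#' genotyping functions can re-call every dosage, and the junction-qPCR
#' plate (`junctions`, with synthetic Ct values) used to call structural
#' elements.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`. `NULL` continues
#'   from the current RNG state (one stream for a whole replicate).
#' @return A list of class `"colony_sim"` with data.frames `colonies`,
#'   `alleles`, `junctions`, and the `config`.
#' @seealso [call_genotypes()] for re-calling dosages from `alleles` and
#'   `junctions`; [simulate_expression()] for attaching phenotypes.
#' @export
simulate_colonies <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  coords <- element_coords()
  lens <- as.integer(names(config$indel_spectrum))
  probs <- as.numeric(config$indel_spectrum)

  col_list <- list(); allele_list <- list(); junc_list <- list()
  colony_counter <- 0L

  for (cond in names(config$conditions)) {
    guides <- config$conditions[[cond]]
    n <- config$colonies_per_condition
    ids <- sprintf("C%05d", colony_counter + seq_len(n))
    colony_counter <- colony_counter + n
    donors <- sprintf("D%02d", rep_len(seq_len(config$donors), n))

    truth <- data.frame(
      colony_id = ids, donor_id = donors, guide_set_id = cond,
      hbg_dosage = 0L, bcl11a_e2_dosage = 0L, bcl11a_e4_dosage = 0L,
      bcl11a_series = 0L, zbtb7a_dosage = 0L,
      hbb_hbd = 0L, hbd_3p5kb = 0L, hbb_3p5kb = 0L,
      hbb_hbd_inv = FALSE, hbd_3p5kb_inv = FALSE, hbb_3p5kb_inv = FALSE,
      exclude_flag = FALSE, exclude_reason = "",
      stringsAsFactors = FALSE
    )

    # single-cut loci: one row per (colony, locus, allele slot)
    single <- intersect(guides, names(.single_cut_guides))
    for (g in single) {
      target_loci <- if (g == "HBG13") c("HBG1_prom", "HBG2_prom")
                     else .single_cut_guides[[g]]
      for (locus in target_loci) {
        crd <- coords[coords$locus == locus, ]
        for (slot in 1:2) {
          edited <- rbinom(n, 1L, config$per_guide_edit_prob) == 1L
          L <- sample(lens, n, replace = TRUE, prob = probs)
          alen <- abs(L)
          del <- L < 0
          start <- ifelse(del, crd$cut_site - alen %/% 2L, crd$cut_site)
          end <- ifelse(del, start + alen, crd$cut_site)
          rec <- data.frame(
            colony_id = ids, locus = locus, allele = slot,
            edit_type = ifelse(edited, "indel", "WT"),
            start = ifelse(edited, start, NA_integer_),
            end = ifelse(edited, end, NA_integer_),
            edited_bases = ifelse(edited, alen, 0L),
            stringsAsFactors = FALSE
          )
          allele_list[[length(allele_list) + 1L]] <- rec

          if (locus %in% c("HBG1_prom", "HBG2_prom")) {
            # bases of the edit falling inside the 13 bp element
            in_win <- ifelse(del,
              pmax(0L, pmin(end, crd$element_end) -
                        pmax(start, crd$element_start)),
              ifelse(start >= crd$element_start & start < crd$element_end,
                     alen, 0L))
            truth$hbg_dosage <- truth$hbg_dosage +
              as.integer(edited & in_win > 2L)
          } else if (locus == "BCL11A_e2") {
            truth$bcl11a_e2_dosage <- truth$bcl11a_e2_dosage +
              as.integer(edited & alen %% 3L != 0L)
          } else if (locus == "BCL11A_e4") {
            truth$bcl11a_e4_dosage <- truth$bcl11a_e4_dosage +
              as.integer(edited & alen %% 3L != 0L)
          } else if (locus == "ZBTB7A") {
            truth$zbtb7a_dosage <- truth$zbtb7a_dosage +
              as.integer(edited & alen %% 3L != 0L)
          }
        }
      }
    }

    # BCL11A allelic series: het e2 = 1, het e4 = 2, biallelic = 3
    a <- truth$bcl11a_e2_dosage; b <- truth$bcl11a_e4_dosage
    truth$bcl11a_series <- ifelse(a + b == 0L, 0L,
                           ifelse(a == 1L & b == 0L, 1L,
                           ifelse(a == 0L & b == 1L, 2L,
                           ifelse(a >= 2L | b >= 2L, 3L, NA_integer_))))
    amb <- is.na(truth$bcl11a_series)
    truth$exclude_flag[amb] <- TRUE
    truth$exclude_reason[amb] <- "ambiguous_bcl11a_series"

    # paired-guide structural elements via junction qPCR
    paired <- intersect(guides, names(.paired_guides))
    for (g in paired) {
      el <- .paired_guides[[g]]
      states <- matrix(sample(c("deleted", "inverted", "intact"), 2L * n,
                              replace = TRUE,
                              prob = c(config$paired_deletion_prob,
                                       config$paired_inversion_prob,
                                       1 - config$paired_deletion_prob -
                                           config$paired_inversion_prob)),
                       nrow = n)
      n_del <- rowSums(states == "deleted")
      any_inv <- rowSums(states == "inverted") > 0L
      any_intact <- rowSums(states == "intact") > 0L
      truth[[el]] <- as.integer(n_del)
      truth[[paste0(el, "_inv")]] <- any_inv
      junc_list[[length(junc_list) + 1L]] <- data.frame(
        colony_id = ids, element = el,
        internal_ct = ifelse(any_intact, runif(n, 24, 28), runif(n, 36, 39.5)),
        deletion_junction_ct = ifelse(n_del > 0L, runif(n, 24, 28),
                                      runif(n, 36, 39.5)),
        inversion_junction_ct = ifelse(any_inv, runif(n, 24, 28),
                                       runif(n, 36, 39.5)),
        stringsAsFactors = FALSE
      )
    }

    # whole HBG1-to-HBB region deletion artifact when promoter guides are
    # combined with beta-locus paired guides (cuts spanning HBG1/2 to
    # HBB); a region-scan junction assay row records it so genotyping can
    # re-call the exclusion
    spans_region <- "HBG13" %in% guides &&
      length(intersect(guides, names(.paired_guides))) >= 1L
    if (spans_region) {
      hit <- rbinom(n, 1L, config$whole_region_del_prob) == 1L
      truth$exclude_flag[hit] <- TRUE
      truth$exclude_reason[hit] <- "whole_region_deletion"
      junc_list[[length(junc_list) + 1L]] <- data.frame(
        colony_id = ids, element = "hbg_hbb_region",
        internal_ct = ifelse(hit, runif(n, 36, 39.5), runif(n, 24, 28)),
        deletion_junction_ct = ifelse(hit, runif(n, 24, 28),
                                      runif(n, 36, 39.5)),
        inversion_junction_ct = runif(n, 36, 39.5),
        stringsAsFactors = FALSE
      )
    }

    col_list[[length(col_list) + 1L]] <- truth
  }

  colonies <- do.call(rbind, col_list)
  rownames(colonies) <- NULL
  alleles <- do.call(rbind, allele_list)
  if (is.null(alleles))
    alleles <- data.frame(colony_id = character(), locus = character(),
                          allele = integer(), edit_type = character(),
                          start = integer(), end = integer(),
                          edited_bases = integer())
  junctions <- do.call(rbind, junc_list)
  if (is.null(junctions))
    junctions <- data.frame(colony_id = character(), element = character(),
                            internal_ct = numeric(),
                            deletion_junction_ct = numeric(),
                            inversion_junction_ct = numeric())
  rownames(alleles) <- rownames(junctions) <- NULL
  attr(colonies, "control_sets") <-
    names(config$conditions)[vapply(config$conditions,
                                    function(g) setequal(g, "AAVS1"), TRUE)]
  structure(list(colonies = colonies, alleles = alleles,
                 junctions = junctions, config = config),
            class = "colony_sim")
}

#' @export
print.colony_sim <- function(x, ...) {
  cat("Synthetic colony study:", nrow(x$colonies), "colonies,",
      length(unique(x$colonies$guide_set_id)), "conditions,",
      length(unique(x$colonies$donor_id)), "donors\n")
  cat("  excluded:", sum(x$colonies$exclude_flag), "colonies\n")
  invisible(x)
}

#' Simulate globin expression from colony genotypes
#'
#' Realizes the mixed-model data-generating process
#' `y = X beta + Z u + e`: the linear predictor is the phenotype model's
#' baseline plus dosage main effects and pairwise interaction products,
#' donor and guide-set random intercepts are drawn as independent normals,
#' and residual noise is added per colony. On the `"identity"` scale the
#' response is the HBG1/2 fraction of beta-like mRNA, clipped to `[0, 1]`;
#' on the `"log"` scale the predictor acts on the log fraction. The HBB
#' fraction is the complement. Total beta-like expression relative to the
#' HBA1/2 control, and the Sanger G:A peak pair that splits HBG between
#' HBG1 and HBG2, are drawn around realistic values so the quantification
#' functions can be exercised end to end.
#'
#' @param colonies Colony genotype data.frame (from [simulate_colonies()]
#'   or [call_genotypes()]); must contain every dosage variable the model
#'   references.
#' @param model A [phenotype_model()].
#' @param seed Integer seed.
#' @param clip Clip identity-scale fractions to `[0, 1]` (the default,
#'   since a fraction of beta-like mRNA is a proportion). `FALSE` leaves
#'   the raw Gaussian linear-model response, the exact distribution the
#'   mixed model assumes, which is what calibration experiments for the
#'   estimator should draw from.
#' @return Data.frame with one row per colony: `hbg_fraction`,
#'   `hbb_fraction` (proportions of beta-like mRNA), `hbg_rel`, `hbb_rel`,
#'   `hbg1_rel`, `hbg2_rel` (relative to HBA1/2), and Sanger peak heights
#'   `g_peak`, `a_peak`.
#' @export
simulate_expression <- function(colonies, model = phenotype_model(),
                                seed = 1L, clip = TRUE) {
  if (inherits(colonies, "colony_sim")) colonies <- colonies$colonies
  stopifnot(inherits(model, "phenotype_model"))
  int_names <- names(model$interaction_effects)
  vars <- union(names(model$main_effects),
                if (length(int_names))
                  unlist(strsplit(int_names, ":", fixed = TRUE))
                else character(0))
  missing_vars <- setdiff(vars, names(colonies))
  if (length(missing_vars))
    stop("genotype table lacks dosage column(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(colonies)

  base <- if (model$response_scale == "log")
    log(model$baseline_hbg_fraction) else model$baseline_hbg_fraction
  eta <- rep(base, n)
  for (nm in names(model$main_effects)) {
    d <- colonies[[nm]]
    d[is.na(d)] <- 0
    eta <- eta + model$main_effects[[nm]] * d
  }
  for (nm in int_names) {
    pr <- strsplit(nm, ":", fixed = TRUE)[[1]]
    d1 <- colonies[[pr[1]]]; d2 <- colonies[[pr[2]]]
    d1[is.na(d1)] <- 0; d2[is.na(d2)] <- 0
    eta <- eta + model$interaction_effects[[nm]] * d1 * d2
  }

  donor_lv <- unique(colonies$donor_id)
  u_donor <- setNames(rnorm(length(donor_lv), 0, model$donor_sd), donor_lv)
  guide_lv <- unique(colonies$guide_set_id)
  u_guide <- setNames(rnorm(length(guide_lv), 0, model$guide_sd), guide_lv)
  ctrl <- attr(colonies, "control_sets")
  if (!is.null(ctrl)) u_guide[names(u_guide) %in% ctrl] <- 0

  y <- eta + u_donor[colonies$donor_id] + u_guide[colonies$guide_set_id] +
    rnorm(n, 0, model$residual_sd)
  frac <- if (model$response_scale == "log") exp(y) else y
  if (clip) frac <- pmin(1, pmax(0, frac))

  total_rel <- exp(rnorm(n, log(1.5), 0.1))
  hbg1_share <- pmin(0.95, pmax(0.05, rnorm(n, 0.5, 0.05)))
  hbg_rel <- total_rel * pmax(frac, 0)
  data.frame(
    colony_id = colonies$colony_id,
    hbg_fraction = frac, hbb_fraction = 1 - frac,
    hbg_rel = hbg_rel, hbb_rel = total_rel * pmax(1 - frac, 0),
    hbg1_rel = hbg_rel * hbg1_share, hbg2_rel = hbg_rel * (1 - hbg1_share),
    g_peak = 100 * hbg1_share, a_peak = 100 * (1 - hbg1_share),
    stringsAsFactors = FALSE
  )
}

#' Synthesize a qPCR plate from simulated expression
#'
#' Inverts the delta-Ct relation used by [quantify_plate()]: a reference
#' (HBA1/2) Ct is drawn per colony and the HBG1/2 and HBB Cts are placed
#' at `ct_ref - log(rel) / log(efficiency)` so that quantification
#' reproduces the simulated relative expression. With `rep_sd = 0`
#' (default) the round trip is exact to numerical precision; positive
#' `rep_sd` adds independent technical-replicate noise.
#'
#' @param expression Output of [simulate_expression()].
#' @param efficiency Amplification factor per cycle.
#' @param replicates Technical replicates per (sample, target).
#' @param rep_sd Replicate Ct noise standard deviation (cycles).
#' @param seed Integer seed.
#' @return Long-format plate data.frame: `sample_id`, `target`
#'   (`"HBA1_2"`, `"HBG1_2"`, `"HBB"`), `replicate`, `ct`. Relative
#'   expression of zero yields a missing Ct (no amplification).
#' @export
simulate_qpcr_plate <- function(expression, efficiency = 2,
                                replicates = 2L, rep_sd = 0, seed = 1L) {
  set.seed(seed)
  n <- nrow(expression)
  ct_ref <- runif(n, 18, 22)
  ct_for <- function(rel) ifelse(rel > 0,
                                 ct_ref - log(rel) / log(efficiency),
                                 NA_real_)
  base <- data.frame(
    sample_id = rep(expression$colony_id, 3L),
    target = rep(c("HBA1_2", "HBG1_2", "HBB"), each = n),
    ct = c(ct_ref, ct_for(expression$hbg_rel), ct_for(expression$hbb_rel)),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    b <- base
    b$replicate <- r
    if (rep_sd > 0) b$ct <- b$ct + rnorm(nrow(b), 0, rep_sd)
    b
  }))
  rownames(out) <- NULL
  out[, c("sample_id", "target", "replicate", "ct")]
}

#' Simulate chromatin interaction records for two conditions
#'
#' Distributes a fixed number of informative read pairs per bait over its
#' target regions by multinomial sampling around the profile's expected
#' count proportions, and attaches a significance (BF) score to each
#' record such that a configurable fraction falls below the BF >= 20
#' filtering threshold.
#'
#' @param profile Data.frame with one row per (condition, bait, target):
#'   columns `condition`, `bait_id`, `bait_chrom`, `bait_start`,
#'   `bait_end`, `target_chrom`, `target_start`, `target_end`, `prop`.
#'   Within each (condition, bait) the `prop` values must sum to 1.
#' @param total_counts Total read-pair count per (condition, bait).
#' @param bf_below_20_fraction Expected fraction of records drawn with a
#'   BF score below 20.
#' @param seed Integer seed.
#' @return Interaction-record data.frame: `condition`, `bait_id`,
#'   `chrom1`, `start1`, `end1` (bait), `chrom2`, `start2`, `end2`
#'   (target), `count`, `bf_score`.
#' @export
simulate_interaction_records <- function(profile,
                                         total_counts = 10000L,
                                         bf_below_20_fraction = 0.1,
                                         seed = 1L) {
  need <- c("condition", "bait_id", "bait_chrom", "bait_start", "bait_end",
            "target_chrom", "target_start", "target_end", "prop")
  miss <- setdiff(need, names(profile))
  if (length(miss))
    stop("profile lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  .check_prob(bf_below_20_fraction, "bf_below_20_fraction")
  key <- interaction(profile$condition, profile$bait_id, drop = TRUE)
  sums <- tapply(profile$prop, key, sum)
  if (any(abs(sums - 1) > 1e-8))
    stop("target proportions must sum to 1 within every (condition, bait); ",
         "offending: ", paste(names(sums)[abs(sums - 1) > 1e-8],
                              collapse = ", "), call. = FALSE)
  set.seed(seed)
  out <- lapply(split(profile, key), function(pf) {
    cnt <- as.integer(rmultinom(1, total_counts, pf$prop))
    low <- runif(nrow(pf)) < bf_below_20_fraction
    data.frame(
      condition = pf$condition, bait_id = pf$bait_id,
      chrom1 = pf$bait_chrom, start1 = pf$bait_start, end1 = pf$bait_end,
      chrom2 = pf$target_chrom, start2 = pf$target_start,
      end2 = pf$target_end,
      count = cnt,
      bf_score = ifelse(low, runif(nrow(pf), 5, 19.99),
                        runif(nrow(pf), 20, 200)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Default capture profile for the beta-globin locus
#'
#' Expected interaction-count proportions for four capture baits (HBB,
#' HBG1/2, the HBD-3.5kb upstream region, and the LCR HS1-5 enhancer) in a
#' wild-type adult-pattern erythroid state (`"WT"`) versus a BCL11A
#' knockout fetal-pattern state (`"KO"`). The shifts encode the hallmark
#' reorganization: loss of HBD-3.5kb / HBG1-2 and LCR / HBB contacts upon
#' BCL11A loss, with gain of LCR / HBG1-2 and 3'HS1 contacts.
#'
#' @return A profile data.frame accepted by
#'   [simulate_interaction_records()].
#' @export
default_capture_profile <- function() {
  regions <- list(
    HS3p   = c(5226000L, 5227200L),
    HBB    = c(5246696L, 5248301L),
    HBD35  = c(5255500L, 5259400L),
    HBG    = c(5269309L, 5276395L),
    LCR    = c(5290000L, 5311000L)
  )
  spec <- list(
    WT = list(
      HBB   = c(LCR = 0.50, HBD35 = 0.25, HBG = 0.10, HS3p = 0.15),
      HBG   = c(HBD35 = 0.45, LCR = 0.20, HBB = 0.20, HS3p = 0.15),
      HBD35 = c(HBG = 0.45, LCR = 0.25, HBB = 0.20, HS3p = 0.10),
      LCR   = c(HBB = 0.50, HBG = 0.20, HBD35 = 0.20, HS3p = 0.10)
    ),
    KO = list(
      HBB   = c(LCR = 0.20, HBD35 = 0.25, HBG = 0.25, HS3p = 0.30),
      HBG   = c(HBD35 = 0.05, LCR = 0.55, HBB = 0.15, HS3p = 0.25),
      HBD35 = c(HBG = 0.05, LCR = 0.35, HBB = 0.20, HS3p = 0.40),
      LCR   = c(HBB = 0.20, HBG = 0.55, HBD35 = 0.05, HS3p = 0.20)
    )
  )
  rows <- list()
  for (cond in names(spec)) for (bait in names(spec[[cond]])) {
    pr <- spec[[cond]][[bait]]
    for (tg in names(pr)) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, bait_id = bait,
        bait_chrom = "chr11", bait_start = regions[[bait]][1],
        bait_end = regions[[bait]][2],
        target_chrom = "chr11", target_start = regions[[tg]][1],
        target_end = regions[[tg]][2],
        prop = unname(pr[tg]), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
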