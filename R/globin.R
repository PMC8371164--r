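#' Relative expression from qPCR Ct values
#'
#' Delta-Ct quantification against an endogenous control:
#' `efficiency^(ct_ref - ct_target)`. With the default per-cycle
#' amplification factor of 2 this is the usual `2^-dCt`. The result is
#' shift-invariant: adding a constant to both Cts leaves it unchanged.
#' Non-finite Cts propagate as missing values.
#'
#' @param ct_target Ct of the gene of interest (cycles).
#' @param ct_ref Ct of the endogenous control (here HBA1/2).
#' @param efficiency Amplification factor per cycle, in (1, 2.2].
#' @return Dimensionless expression ratio (vectorized).
#' @examples
#' relative_expression(22, 20)            # 0.25
#' relative_expression(22, 20, 1.9)       # 1.9^-2
#' @export
relative_expression <- function(ct_target, ct_ref, efficiency = 2) {
  if (any(efficiency <= 1 | efficiency > 2.2))
    stop("`efficiency` must lie in (1, 2.2]", call. = FALSE)
  out <- efficiency^(ct_ref - ct_target)
  out[!is.finite(ct_target) | !is.finite(ct_ref)] <- NA_real_
  out
}

#' Fraction of beta-like globin mRNA
#'
#' Splits total beta-like globin expression into the HBG1/2 (fetal) and
#' HBB (adult) percentages: `100 * hbg / (hbg + hbb)` and its complement.
#' The two outputs always sum to 100. Both inputs zero is undefined and
#' returns missing values.
#'
#' @param hbg_rel,hbb_rel Non-negative expression ratios relative to the
#'   same control (vectorized).
#' @return Data.frame with `hbg_pct` and `hbb_pct`.
#' @examples
#' beta_like_fraction(0.8, 3.2)  # 20 / 80, the unedited baseline regime
#' @export
beta_like_fraction <- function(hbg_rel, hbb_rel) {
  if (any(hbg_rel < 0, na.rm = TRUE) || any(hbb_rel < 0, na.rm = TRUE))
    stop("expression ratios must be >= 0", call. = FALSE)
  tot <- hbg_rel + hbb_rel
  hbg_pct <- ifelse(tot > 0, 100 * hbg_rel / tot, NA_real_)
  data.frame(hbg_pct = hbg_pct, hbb_pct = 100 - hbg_pct)
}

#' Split HBG expression between HBG1 and HBG2
#'
#' The HBG1/2 qPCR assay amplifies both homologous genes; their relative
#' contribution is read from the G (HBG1) : A (HBG2) nucleotide peak
#' heights of the Sanger chromatogram at the discriminating position.
#' The split conserves the total: `hbg1 + hbg2 = hbg_rel`.
#'
#' @param hbg_rel Combined HBG1/2 relative expression.
#' @param g_peak,a_peak Chromatogram peak heights (arbitrary units, each
#'   non-negative and not both 0).
#' @return Data.frame with `hbg1_rel` and `hbg2_rel`.
#' @examples
#' split_hbg(0.8, 3, 1)  # 0.6 / 0.2
#' @export
split_hbg <- function(hbg_rel, g_peak, a_peak) {
  if (any(g_peak < 0, na.rm = TRUE) || any(a_peak < 0, na.rm = TRUE))
    stop("peak heights must be >= 0", call. = FALSE)
  tot <- g_peak + a_peak
  share <- ifelse(tot > 0, g_peak / tot, NA_real_)
  data.frame(hbg1_rel = hbg_rel * share, hbg2_rel = hbg_rel * (1 - share))
}

#' Quantify globin expression from a qPCR plate
#'
#' Averages technical-replicate Cts per (sample, target), computes HBG1/2
#' and HBB expression relative to the HBA1/2 endogenous control by the
#' delta-Ct method, and derives the beta-like fractions. Samples missing
#' the control are dropped with a warning; missing target Cts propagate
#' as missing ratios. If `peaks` is supplied, the combined HBG signal is
#' split into HBG1 and HBG2 by chromatogram peak ratio.
#'
#' @param plate Long-format data.frame: `sample_id`, `target` (must use
#'   `"HBA1_2"`, `"HBG1_2"`, `"HBB"`), `ct`; extra columns ignored.
#' @param efficiency Amplification factor per cycle.
#' @param peaks Optional data.frame `sample_id`, `g_peak`, `a_peak`.
#' @return Data.frame per sample: `colony_id`, `hbg_rel`, `hbb_rel`,
#'   `hbg_fraction`, `hbb_fraction` (proportions in `[0, 1]`), `hbg_pct`,
#'   `hbb_pct` (percent of beta-like mRNA), and `hbg1_rel`, `hbg2_rel`
#'   when peaks are given.
#' @export
quantify_plate <- function(plate, efficiency = 2, peaks = NULL) {
  need <- c("sample_id", "target", "ct")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop("plate lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  known <- c("HBA1_2", "HBG1_2", "HBB")
  bad <- setdiff(unique(plate$target), known)
  if (length(bad))
    stop("unknown target(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(known, collapse = ", "), call. = FALSE)
  mean_ct <- aggregate(ct ~ sample_id + target,
                       data = plate[!is.na(plate$ct), , drop = FALSE],
                       FUN = mean)
  wide <- stats::reshape(mean_ct, idvar = "sample_id", timevar = "target",
                         direction = "wide")
  names(wide) <- sub("^ct\\.", "", names(wide))
  for (t in known) if (!t %in% names(wide)) wide[[t]] <- NA_real_
  no_ref <- is.na(wide$HBA1_2)
  if (any(no_ref)) {
    warning(sum(no_ref), " sample(s) dropped: no HBA1/2 control Ct")
    wide <- wide[!no_ref, ]
  }
  out <- data.frame(
    colony_id = wide$sample_id,
    hbg_rel = relative_expression(wide$HBG1_2, wide$HBA1_2, efficiency),
    hbb_rel = relative_expression(wide$HBB, wide$HBA1_2, efficiency),
    stringsAsFactors = FALSE
  )
  # an undetected transcript with a detected control is absence, not missing
  out$hbg_rel[is.na(wide$HBG1_2)] <- 0
  out$hbb_rel[is.na(wide$HBB)] <- 0
  frac <- beta_like_fraction(out$hbg_rel, out$hbb_rel)
  out$hbg_pct <- frac$hbg_pct
  out$hbb_pct <- frac$hbb_pct
  out$hbg_fraction <- frac$hbg_pct / 100
  out$hbb_fraction <- frac$hbb_pct / 100
  if (!is.null(peaks)) {
    m <- match(out$colony_id, peaks$sample_id)
    sp <- split_hbg(out$hbg_rel, peaks$g_peak[m], peaks$a_peak[m])
    out$hbg1_rel <- sp$hbg1_rel
    out$hbg2_rel <- sp$hbg2_rel
  }
  rownames(out) <- NULL
  out
}
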