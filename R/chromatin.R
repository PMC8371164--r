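#' Filter chromatin interaction records by significance score
#'
#' Only significant long-range interactions enter the quantitative
#' analyses: records are kept when their BF score is at least `min_bf`
#' (inclusive at the boundary, so a score of exactly 20 is kept under the
#' default).
#'
#' @param records Interaction-record data.frame with a `bf_score` column.
#' @param min_bf Minimum BF score (default 20).
#' @return The filtered data.frame.
#' @export
filter_significant <- function(records, min_bf = 20) {
  if (!"bf_score" %in% names(records))
    stop("records lack a `bf_score` column", call. = FALSE)
  out <- records[!is.na(records$bf_score) & records$bf_score >= min_bf, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative interaction frequency per kilobase
#'
#' For one capture bait, the per-target relative interaction frequency is
#' `count x 10^6 / (bait_size_bp x total count from the bait)`. The
#' values are scale-invariant in the counts (doubling every count changes
#' nothing) and conserve `sum(rif) = 10^6 / bait_size_bp` exactly.
#' Records should already be significance-filtered (filter first, then
#' normalize over the filtered total).
#'
#' @param records Interaction records for one bait: columns `count` and
#'   target coordinates; multiple baits are allowed if `bait_id` is
#'   present, each normalized over its own total.
#' @param bait_size_bp Bait region size in bp, > 0. If `NULL` and the
#'   records carry `start1`/`end1`, the size of the union interval of the
#'   bait anchors is used (relevant for multiplexed baits with several
#'   sgRNA anchor windows).
#' @return The records with an added `rif` column.
#' @export
relative_interaction_frequency <- function(records, bait_size_bp = NULL) {
  if (!"count" %in% names(records))
    stop("records lack a `count` column", call. = FALSE)
  if (any(records$count < 0))
    stop("counts must be >= 0", call. = FALSE)
  split_key <- if ("bait_id" %in% names(records))
    records$bait_id else rep("bait", nrow(records))
  idx <- split(seq_len(nrow(records)), split_key)
  out <- lapply(names(idx), function(b) {
    rb <- records[idx[[b]], , drop = FALSE]
    size <- bait_size_bp
    if (is.null(size)) {
      if (!all(c("start1", "end1") %in% names(rb)))
        stop("supply `bait_size_bp` or bait coordinates start1/end1",
             call. = FALSE)
      size <- max(rb$end1) - min(rb$start1)
    }
    if (size <= 0) stop("bait size must be > 0", call. = FALSE)
    tot <- sum(rb$count)
    if (tot == 0)
      stop("zero total interaction count for bait ", b,
           "; relative frequency undefined", call. = FALSE)
    rb$rif <- rb$count * 1e6 / (size * tot)
    rb
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' 3C ligation frequency relative to the TUBA1A control
#'
#' Per biological replicate, the relative ligation frequency of a test
#' fragment with the anchor is `efficiency^(ct_control - ct_ligation)`,
#' normalizing each ligation qPCR to the control interaction in the
#' TUBA1A gene from the same replicate. Results are summarized per
#' fragment as the mean and SEM (`sd / sqrt(r)`) over replicates; a
#' single replicate yields a defined mean and a missing SEM.
#'
#' @param measurements Data.frame with columns `fragment`, `replicate`,
#'   `ligation_ct`, `control_ct`.
#' @param efficiency Amplification factor per cycle.
#' @return Data.frame per fragment: `mean_rel`, `sem`, `n_replicates`.
#' @export
threec_relative <- function(measurements, efficiency = 2) {
  need <- c("fragment", "replicate", "ligation_ct", "control_ct")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurements lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(measurements) == 0)
    stop("at least one replicate measurement is required", call. = FALSE)
  if (anyNA(measurements$control_ct))
    stop("every replicate needs a control (TUBA1A) Ct", call. = FALSE)
  rel <- relative_expression(measurements$ligation_ct,
                             measurements$control_ct, efficiency)
  agg <- split(rel, measurements$fragment)
  out <- data.frame(
    fragment = names(agg),
    mean_rel = vapply(agg, mean, numeric(1)),
    sem = vapply(agg, function(v)
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    n_replicates = vapply(agg, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Compare normalized interaction profiles between two conditions
#'
#' Pairs per-target relative interaction frequencies (e.g. wild-type vs
#' knockout) by bait and target interval and reports their difference and
#' ratio. Both conditions must cover the same (bait, target) set;
#' mismatches are an error listing the offending intervals.
#'
#' @param rif_a,rif_b Outputs of [relative_interaction_frequency()] for
#'   the two conditions (must contain `chrom2`, `start2`, `end2`, `rif`,
#'   and `bait_id` if multi-bait).
#' @param labels Length-2 character vector naming the conditions.
#' @return Data.frame per (bait, target): the two rif values, their
#'   `diff` (B - A) and `ratio` (B / A; `Inf` when A is 0 and B is not,
#'   `NaN` when both are 0).
#' @export
compare_conditions <- function(rif_a, rif_b, labels = c("A", "B")) {
  keycols <- intersect(c("bait_id", "chrom2", "start2", "end2"),
                       union(names(rif_a), names(rif_b)))
  key <- function(d) do.call(paste, c(d[keycols], sep = "|"))
  ka <- key(rif_a); kb <- key(rif_b)
  only_a <- setdiff(ka, kb); only_b <- setdiff(kb, ka)
  if (length(only_a) || length(only_b))
    stop("target sets differ between conditions; only in ", labels[1],
         ": ", paste(only_a, collapse = ", "), "; only in ", labels[2],
         ": ", paste(only_b, collapse = ", "), call. = FALSE)
  m <- match(ka, kb)
  out <- rif_a[keycols]
  out[[paste0("rif_", labels[1])]] <- rif_a$rif
  out[[paste0("rif_", labels[2])]] <- rif_b$rif[m]
  out$diff <- rif_b$rif[m] - rif_a$rif
  out$ratio <- rif_b$rif[m] / rif_a$rif
  rownames(out) <- NULL
  out
}
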