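#' Score disruption of the HBG promoter 13 bp element
#'
#' An edit at an HBG1/HBG2 proximal promoter allele counts as disruptive
#' when more than 2 bp of the edit fall inside the 13 bp BCL11A-binding
#' element (positions -101 to -114 relative to the TSS). Substitutions
#' count toward the edited-base total in the same way as indels. For a
#' spanning edit (deletion or substitution run) the contribution is the
#' width of the overlap between the edited interval and the window; for an
#' insertion (zero-width interval) all inserted bases count when the
#' insertion point lies inside the window.
#'
#' @param edit One allele record: a list or one-row data.frame with
#'   `locus`, `edit_type` (`"WT"`, `"indel"` or `"substitution"`),
#'   `start`, `end` (0-based half-open, amplicon frame) and
#'   `edited_bases`.
#' @param window Integer vector `c(start, end)` of the 13 bp element on
#'   the same frame; defaults to the packaged coordinates.
#' @return `TRUE` iff the edit is disruptive.
#' @examples
#' win <- c(100, 113)
#' # the recurrent 13 bp deletion removes the element entirely
#' call_promoter_disruption(list(locus = "HBG1_prom", edit_type = "indel",
#'                               start = 101, end = 114, edited_bases = 13),
#'                          win)
#' @export
call_promoter_disruption <- function(edit, window = NULL) {
  if (is.null(window)) {
    crd <- element_coords()
    crd <- crd[crd$locus == "HBG1_prom", ]
    window <- c(crd$element_start, crd$element_end)
  }
  if (!edit$locus %in% c("HBG1_prom", "HBG2_prom"))
    stop("promoter disruption rule applies only to HBG promoter alleles, ",
         "got locus ", edit$locus, call. = FALSE)
  .bases_in_window(edit$edit_type, edit$start, edit$end,
                   edit$edited_bases, window[1], window[2]) > 2
}

# vectorized count of edited bases intersecting [ws, we)
.bases_in_window <- function(edit_type, start, end, edited_bases, ws, we) {
  out <- numeric(length(edit_type))
  ins <- !is.na(start) & !is.na(end) & start == end & edit_type != "WT"
  span <- !is.na(start) & !is.na(end) & start < end & edit_type != "WT"
  out[ins] <- ifelse(start[ins] >= ws & start[ins] < we,
                     edited_bases[ins], 0)
  out[span] <- pmax(0, pmin(end[span], we) - pmax(start[span], ws))
  out
}

#' Count disrupted HBG promoter alleles in a colony
#'
#' @param calls Logical vector of exactly four per-allele disruption calls
#'   (two HBG1 and two HBG2 promoter alleles); the two promoters
#'   contribute symmetrically.
#' @return Integer dosage 0-4.
#' @export
count_hbg_dosage <- function(calls) {
  if (length(calls) != 4L || !is.logical(calls) || anyNA(calls))
    stop("expected exactly 4 non-missing logical promoter calls ",
         "(2x HBG1, 2x HBG2)", call. = FALSE)
  sum(calls)
}

#' Encode BCL11A perturbations
#'
#' Two codings are used in the models. The allelic series ranks
#' perturbation severity: 0 = no frameshift, 1 = heterozygous exon-2
#' frameshift, 2 = heterozygous exon-4 frameshift (exon-4 heterozygotes
#' act beyond haploinsufficiency), 3 = biallelic frameshift. The exon-2
#' dosage coding simply counts exon-2 frameshift alleles (0-2). Colonies
#' heterozygous at both exons simultaneously have no slot in the allelic
#' series and are returned as `NA` (callers exclude them).
#'
#' @param e2,e4 Logical vectors of per-allele frameshift calls (length 2
#'   each) for exon 2 and exon 4.
#' @param scheme `"allelic_series"` or `"e2_dosage"`.
#' @return Integer code (`NA` for the ambiguous double-heterozygote under
#'   `"allelic_series"`).
#' @export
code_bcl11a <- function(e2, e4 = c(FALSE, FALSE),
                        scheme = c("allelic_series", "e2_dosage")) {
  scheme <- match.arg(scheme)
  if (length(e2) != 2L || length(e4) != 2L)
    stop("expected 2 allele calls per exon", call. = FALSE)
  a <- sum(e2); b <- sum(e4)
  if (scheme == "e2_dosage") return(a)
  .bcl11a_series(a, b)
}

.bcl11a_series <- function(a, b) {
  ifelse(a + b == 0L, 0L,
  ifelse(a == 1L & b == 0L, 1L,
  ifelse(a == 0L & b == 1L, 2L,
  ifelse(a >= 2L | b >= 2L, 3L, NA_integer_))))
}

#' Count ZBTB7A frameshift alleles
#'
#' @param calls Logical vector of exactly two per-allele frameshift calls.
#' @return Integer dosage 0-2.
#' @export
code_zbtb7a <- function(calls) {
  if (length(calls) != 2L || !is.logical(calls) || anyNA(calls))
    stop("expected exactly 2 non-missing logical allele calls",
         call. = FALSE)
  sum(calls)
}

#' Call structural-variant zygosity from junction qPCR
#'
#' Deletions and inversions of the beta-globin locus elements (HBB-HBD,
#' HBD-3.5kb, HBB-3.5kb) are identified by three qPCR assays: an internal
#' amplicon inside the element, a deletion-junction amplicon and an
#' inversion-junction amplicon. Zygosity follows from presence/absence:
#' internal only = intact (dosage 0); internal + deletion junction =
#' heterozygous deletion (1); deletion junction without internal =
#' homozygous deletion (2), unless an inversion junction is also present,
#' in which case one allele is deleted and one inverted (dosage 1).
#' An inversion junction sets the inversion flag. No amplification in any
#' assay is uninterpretable and flagged for exclusion.
#'
#' @param internal_present,deletion_junction_present,inversion_junction_present
#'   Logical vectors (recycled to a common length).
#' @return Data.frame with `deletion_dosage` (0-2), `inversion_flag`,
#'   `exclude_flag`, `exclude_reason`.
#' @export
call_structural <- function(internal_present, deletion_junction_present,
                            inversion_junction_present) {
  n <- max(length(internal_present), length(deletion_junction_present),
           length(inversion_junction_present))
  int <- rep_len(internal_present, n)
  del <- rep_len(deletion_junction_present, n)
  inv <- rep_len(inversion_junction_present, n)
  if (anyNA(int) || anyNA(del) || anyNA(inv))
    stop("all three assay results must be present", call. = FALSE)
  dosage <- ifelse(del, ifelse(int, 1L, ifelse(inv, 1L, 2L)), 0L)
  excl <- !int & !del & !inv
  data.frame(
    deletion_dosage = dosage,
    inversion_flag = inv,
    exclude_flag = excl,
    exclude_reason = ifelse(excl, "no_amplification", ""),
    stringsAsFactors = FALSE
  )
}

#' Convert junction qPCR Ct values to presence calls
#'
#' Presence is qualitative: amplification with Ct strictly below the
#' cutoff. Missing Ct (no amplification recorded) is absence.
#'
#' @param ct Numeric Ct vector.
#' @param cutoff Presence cutoff in cycles (default 35).
#' @return Logical vector.
#' @export
junction_presence <- function(ct, cutoff = 35) {
  !is.na(ct) & ct < cutoff
}

#' Genotype colonies from allele records and junction qPCR
#'
#' Applies every genotype-coding rule to a study's worth of colonies:
#' the >2 bp window rule for HBG promoter disruption (dosage 0-4 over the
#' four promoter alleles), frameshift calling (indel length not a
#' multiple of 3) and series coding for BCL11A and ZBTB7A, and junction
#' qPCR zygosity for the structural elements. Colonies with an ambiguous
#' BCL11A double-heterozygote, an uninterpretable junction assay, or a
#' whole HBG1-to-HBB region deletion (element `"hbg_hbb_region"` in the
#' junction table) are flagged for exclusion with a reason.
#'
#' @param alleles Allele-record data.frame (`colony_id`, `locus`,
#'   `allele`, `edit_type`, `start`, `end`, `edited_bases`).
#' @param junctions Optional junction qPCR data.frame (`colony_id`,
#'   `element`, and either presence logicals `internal_present`,
#'   `deletion_junction_present`, `inversion_junction_present` or Ct
#'   columns `internal_ct`, `deletion_junction_ct`,
#'   `inversion_junction_ct`).
#' @param colony_info Optional data.frame mapping `colony_id` to
#'   `donor_id` and `guide_set_id`.
#' @param coords Element coordinate table, see [element_coords()].
#' @param ct_cutoff Presence Ct cutoff for junction assays.
#' @return A colony genotype data.frame with one row per colony: dosage
#'   codes, inversion flags, `exclude_flag` and `exclude_reason`.
#' @export
call_genotypes <- function(alleles, junctions = NULL, colony_info = NULL,
                           coords = element_coords(), ct_cutoff = 35) {
  need <- c("colony_id", "locus", "allele", "edit_type", "start", "end",
            "edited_bases")
  miss <- setdiff(need, names(alleles))
  if (length(miss))
    stop("allele table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- unique(c(alleles$colony_id, junctions$colony_id))
  geno <- data.frame(colony_id = ids, stringsAsFactors = FALSE)

  count_by_colony <- function(cids, hit) {
    out <- setNames(integer(length(ids)), ids)
    if (length(cids)) {
      agg <- rowsum(as.integer(hit), cids)
      out[rownames(agg)] <- agg[, 1]
    }
    out
  }

  # HBG promoter dosage
  hbg <- alleles[alleles$locus %in% c("HBG1_prom", "HBG2_prom"), ]
  if (nrow(hbg)) {
    tab <- table(hbg$colony_id)
    if (any(tab != 4L))
      stop("each colony with HBG promoter records needs exactly 4 alleles; ",
           "offending: ", paste(head(names(tab)[tab != 4L]), collapse = ", "),
           call. = FALSE)
    crd <- coords[coords$locus == "HBG1_prom", ]
    disruptive <- .bases_in_window(hbg$edit_type, hbg$start, hbg$end,
                                   hbg$edited_bases,
                                   crd$element_start, crd$element_end) > 2
    geno$hbg_dosage <- count_by_colony(hbg$colony_id, disruptive)
  } else geno$hbg_dosage <- 0L

  # frameshift-coded loci
  fs <- function(locus) {
    rec <- alleles[alleles$locus == locus, ]
    hit <- rec$edit_type == "indel" & rec$edited_bases %% 3L != 0L
    count_by_colony(rec$colony_id, hit)
  }
  geno$bcl11a_e2_dosage <- fs("BCL11A_e2")
  geno$bcl11a_e4_dosage <- fs("BCL11A_e4")
  geno$bcl11a_series <- .bcl11a_series(geno$bcl11a_e2_dosage,
                                       geno$bcl11a_e4_dosage)
  geno$zbtb7a_dosage <- fs("ZBTB7A")

  geno$exclude_flag <- FALSE
  geno$exclude_reason <- ""
  amb <- is.na(geno$bcl11a_series)
  geno$exclude_flag[amb] <- TRUE
  geno$exclude_reason[amb] <- "ambiguous_bcl11a_series"

  # structural elements from junction qPCR
  for (el in .structural_elements) {
    geno[[el]] <- 0L
    geno[[paste0(el, "_inv")]] <- FALSE
  }
  if (!is.null(junctions) && nrow(junctions)) {
    j <- junctions
    if (!"internal_present" %in% names(j)) {
      j$internal_present <- junction_presence(j$internal_ct, ct_cutoff)
      j$deletion_junction_present <-
        junction_presence(j$deletion_junction_ct, ct_cutoff)
      j$inversion_junction_present <-
        junction_presence(j$inversion_junction_ct, ct_cutoff)
    }
    for (el in intersect(unique(j$element), .structural_elements)) {
      je <- j[j$element == el, ]
      calls <- call_structural(je$internal_present,
                               je$deletion_junction_present,
                               je$inversion_junction_present)
      idx <- match(je$colony_id, geno$colony_id)
      geno[[el]][idx] <- calls$deletion_dosage
      geno[[paste0(el, "_inv")]][idx] <- calls$inversion_flag
      bad <- calls$exclude_flag
      geno$exclude_flag[idx[bad]] <- TRUE
      geno$exclude_reason[idx[bad]] <-
        paste0("no_amplification_", el)
    }
    jr <- j[j$element == "hbg_hbb_region", ]
    if (nrow(jr)) {
      whole <- !jr$internal_present & jr$deletion_junction_present
      idx <- match(jr$colony_id[whole], geno$colony_id)
      geno$exclude_flag[idx] <- TRUE
      geno$exclude_reason[idx] <- "whole_region_deletion"
    }
  }

  if (!is.null(colony_info)) {
    keep <- intersect(c("colony_id", "donor_id", "guide_set_id"),
                      names(colony_info))
    geno <- merge(colony_info[, keep, drop = FALSE], geno,
                  by = "colony_id", sort = FALSE)
  }
  rownames(geno) <- NULL
  geno
}
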