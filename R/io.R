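#' @keywords internal
.check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read and write colony genotype tables
#'
#' Tab-separated, one row per colony, UTF-8, 0-based half-open
#' coordinates throughout. Reading validates the required schema.
#'
#' @param path File path.
#' @param genotypes Colony genotype data.frame.
#' @return `read_colony_table()` returns the validated data.frame.
#' @export
read_colony_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .check_columns(df, c("colony_id", "donor_id", "guide_set_id"),
                 "colony table")
  df
}

#' @rdname read_colony_table
#' @export
write_colony_table <- function(genotypes, path) {
  write.table(genotypes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and write allele-record tables (TSV)
#'
#' @param path File path.
#' @param alleles Allele-record data.frame.
#' @export
read_allele_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .check_columns(df, c("colony_id", "locus", "allele", "edit_type",
                       "start", "end", "edited_bases"), "allele table")
  bad <- which(df$edited_bases < 0)
  if (length(bad))
    stop("allele table: negative edited_bases at data line(s) ",
         paste(head(bad), collapse = ", "), call. = FALSE)
  bad <- which(df$edit_type == "WT" & df$edited_bases != 0)
  if (length(bad))
    stop("allele table: WT allele with edited_bases > 0 at data line(s) ",
         paste(head(bad), collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_allele_table
#' @export
write_allele_table <- function(alleles, path) {
  write.table(alleles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write qPCR plate tables (CSV)
#'
#' Comma-separated long format: `sample_id`, `target`, `ct` (plus
#' optional `replicate`).
#'
#' @param path File path.
#' @param plate Plate data.frame.
#' @export
read_plate <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("sample_id", "target", "ct"), "qPCR plate")
  df
}

#' @rdname read_plate
#' @export
write_plate <- function(plate, path) {
  write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read element coordinates from BED
#'
#' BED3+ with 0-based half-open intervals; the optional 4th column names
#' the element. Malformed intervals are rejected with their line number.
#'
#' @param path BED file path.
#' @return Data.frame `chrom`, `start`, `end` and `name` if present.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop("BED needs at least 3 columns", call. = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start > df$end | df$start < 0)
  if (length(bad))
    stop("BED: malformed interval at line(s) ",
         paste(head(bad), collapse = ", "), call. = FALSE)
  df[seq_len(min(4, ncol(df)))]
}

#' Read and write interaction records (BEDPE-like TSV)
#'
#' Columns `chrom1 start1 end1 chrom2 start2 end2 count bf_score`, with
#' optional leading `condition` and `bait_id`. Negative counts and
#' malformed intervals are rejected with their line number.
#'
#' @param path File path.
#' @param records Interaction-record data.frame.
#' @export
read_bedpe <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .check_columns(df, c("chrom1", "start1", "end1", "chrom2", "start2",
                       "end2", "count", "bf_score"),
                 "interaction record table")
  bad <- which(df$count < 0)
  if (length(bad))
    stop("interaction records: negative count at data line(s) ",
         paste(head(bad), collapse = ", "), call. = FALSE)
  bad <- which(df$start1 > df$end1 | df$start2 > df$end2 |
                 df$start1 < 0 | df$start2 < 0)
  if (length(bad))
    stop("interaction records: malformed interval at data line(s) ",
         paste(head(bad), collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_bedpe
#' @export
write_bedpe <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write amplicon allele sequences as FASTA
#'
#' Reconstructs per-allele amplicon sequences from a reference sequence
#' set and allele edit records (deletions remove the edited interval;
#' insertions insert `edited_bases` N placeholders) and writes them via
#' Biostrings. Intended for export of simulated studies.
#'
#' @param alleles Allele-record data.frame.
#' @param references Named character vector of reference amplicon
#'   sequences, one per locus.
#' @param path Output FASTA path.
#' @export
write_amplicon_fasta <- function(alleles, references, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA export", call. = FALSE)
  seqs <- vapply(seq_len(nrow(alleles)), function(i) {
    a <- alleles[i, ]
    ref <- references[[a$locus]]
    if (is.null(ref)) stop("no reference for locus ", a$locus,
                           call. = FALSE)
    if (a$edit_type == "WT" || is.na(a$start)) return(ref)
    if (a$start == a$end)   # insertion
      paste0(substr(ref, 1, a$start),
             strrep("N", a$edited_bases),
             substr(ref, a$start + 1, nchar(ref)))
    else                    # deletion / substitution span
      paste0(substr(ref, 1, a$start), substr(ref, a$end + 1, nchar(ref)))
  }, character(1))
  names(seqs) <- sprintf("%s|%s|allele%d", alleles$colony_id,
                         alleles$locus, alleles$allele)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a model fit report as JSON
#'
#' Serializes the coefficient table (estimates, standard errors,
#' Satterthwaite df and p-values), variance components and REML
#' log-likelihood of a [colony_lmm()] fit.
#'
#' @param fit A `colony_lmm` fit.
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  s <- summary(fit)
  report <- list(
    formula = deparse(fit$formula),
    n = s$n,
    coefficients = cbind(term = rownames(s$coefficients),
                         as.data.frame(s$coefficients)),
    variance_components = as.list(s$varcomp),
    reml_loglik = s$reml_loglik
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
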