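#' Run the colony analysis pipeline end to end
#'
#' Orchestrates simulation (or ingestion of existing tables), genotype
#' calling, expression quantification, interaction mixed-model fitting
#' and chromatin-profile normalization, writing every intermediate and
#' report under `outdir`. All stages are driven by one configuration
#' (YAML file or equivalent nested list) and a seed, so outputs are
#' reproducible byte for byte.
#'
#' Configuration keys (all optional except `outdir`):
#' `seed`; `outdir`; `simulation` (arguments to [sim_config()]);
#' `phenotype` (arguments to [phenotype_model()]); `inputs` (paths to
#' pre-existing `alleles`, `junctions`, `colony_info`, `plate` tables,
#' used instead of simulating); `thresholds` (`ct_cutoff`, `min_bf`,
#' `efficiency`); `models` (preset names, see [model_formula()]);
#' `response` (response column for the fits); `capture` (logical,
#' run the chromatin stage).
#'
#' @param config Path to a YAML file or a named list.
#' @return Invisibly, a list with the merged colony table, the fits, the
#'   chromatin comparison and the paths of everything written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$outdir))
    stop("config must name an `outdir`", call. = FALSE)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  thr <- config$thresholds %||% list()
  ct_cutoff <- thr$ct_cutoff %||% 35
  min_bf <- thr$min_bf %||% 20
  efficiency <- thr$efficiency %||% 2
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                            sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("hbfedit %s | seed %d",
       as.character(utils::packageVersion("hbfedit")), seed)

  paths <- list()
  if (!is.null(config$inputs)) {
    for (nm in c("alleles", "junctions", "colony_info", "plate")) {
      p <- config$inputs[[nm]]
      if (!is.null(p) && !file.exists(p))
        stop("input file not found: ", p, call. = FALSE)
    }
    logf("stage simulate: skipped (external inputs)")
    alleles <- read_allele_table(config$inputs$alleles)
    junctions <- if (!is.null(config$inputs$junctions))
      read.delim(config$inputs$junctions, stringsAsFactors = FALSE)
    colony_info <- if (!is.null(config$inputs$colony_info))
      read_colony_table(config$inputs$colony_info)
    plate <- read_plate(config$inputs$plate)
  } else {
    sc <- do.call(sim_config, c(config$simulation %||% list(),
                                list(seed = seed)))
    pm <- do.call(phenotype_model, config$phenotype %||% list())
    sim <- simulate_colonies(sc)
    expr <- simulate_expression(sim, pm, seed = seed + 1L)
    plate <- simulate_qpcr_plate(expr, efficiency = efficiency,
                                 seed = seed + 2L)
    alleles <- sim$alleles
    junctions <- sim$junctions
    colony_info <- sim$colonies[c("colony_id", "donor_id",
                                  "guide_set_id")]
    paths$alleles <- write_allele_table(alleles,
                                        file.path(outdir, "alleles.tsv"))
    write.table(junctions, file.path(outdir, "junctions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths$plate <- write_plate(plate, file.path(outdir, "plate.csv"))
    logf("stage simulate: %d colonies, %d allele records",
         nrow(sim$colonies), nrow(alleles))
  }

  geno <- call_genotypes(alleles, junctions, colony_info = colony_info,
                         ct_cutoff = ct_cutoff)
  paths$genotypes <- write_colony_table(geno,
                                        file.path(outdir, "genotypes.tsv"))
  excl <- geno[geno$exclude_flag, c("colony_id", "exclude_reason")]
  logf("stage genotype: %d colonies, %d excluded (%s)", nrow(geno),
       nrow(excl), if (nrow(excl))
         paste(names(table(excl$exclude_reason)),
               table(excl$exclude_reason), collapse = ", ") else "none")

  quant <- quantify_plate(plate, efficiency = efficiency)
  merged <- merge(geno, quant, by = "colony_id", sort = FALSE)
  write.csv(merged, file.path(outdir, "colony_table.csv"),
            row.names = FALSE)
  paths$colony_table <- file.path(outdir, "colony_table.csv")
  logf("stage quantify: %d colonies with expression", nrow(quant))

  models <- config$models %||% c("dd_interaction", "bcl11a_hbg",
                                 "bcl11a_zbtb7a")
  response <- config$response %||% "hbg_fraction"
  ctrl <- attr(colony_info, "control_sets") %||%
    intersect("AAVS1", merged$guide_set_id)
  fits <- list()
  for (m in models) {
    fo <- model_formula(m, response)
    f <- colony_lmm(fo, model_subset(merged, fo, control = ctrl),
                    ref_levels = if (length(ctrl))
                      c(guide_set_id = ctrl[1]))
    fits[[m]] <- f
    paths[[paste0("fit_", m)]] <- write_fit_report(
      f, file.path(outdir, paste0("fit_", m, ".json")))
    prof <- interaction_profile(f)
    write.csv(prof, file.path(outdir, paste0("profile_", m, ".csv")),
              row.names = FALSE)
    logf("stage fit %s: n=%d, logLik=%.2f", m, f$dm$n,
         f$fit$reml_loglik)
  }

  comparison <- NULL
  if (isTRUE(config$capture %||% TRUE)) {
    recs <- simulate_interaction_records(default_capture_profile(),
                                         seed = seed + 3L)
    paths$interactions <- write_bedpe(recs,
                                      file.path(outdir,
                                                "interactions.tsv"))
    sig <- filter_significant(recs, min_bf = min_bf)
    # compare over the (bait, target) pairs significant in both conditions
    key <- with(sig, paste(bait_id, chrom2, start2, end2))
    common <- intersect(key[sig$condition == "WT"],
                        key[sig$condition == "KO"])
    sig <- sig[key %in% common, ]
    rif <- lapply(split(sig, sig$condition),
                  relative_interaction_frequency)
    comparison <- compare_conditions(rif$WT, rif$KO,
                                     labels = c("WT", "KO"))
    write.csv(comparison, file.path(outdir, "rif_comparison.csv"),
              row.names = FALSE)
    paths$rif_comparison <- file.path(outdir, "rif_comparison.csv")
    logf("stage chromatin: %d/%d records pass BF >= %g", nrow(sig),
         nrow(recs), min_bf)
  }

  logf("pipeline complete")
  invisible(list(colony_table = merged, fits = fits,
                 comparison = comparison, paths = paths,
                 log = log_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
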