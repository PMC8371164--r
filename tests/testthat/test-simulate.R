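test_that("configuration validation rejects impossible parameters", {
  expect_error(sim_config(per_guide_edit_prob = 1.2), "probability")
  expect_error(sim_config(indel_spectrum = c("-13" = 0.6, "-1" = 0.3)),
               "sum to 1")
  expect_error(sim_config(indel_spectrum = c("0" = 1)), "non-zero")
  expect_error(sim_config(paired_deletion_prob = 0.7,
                          paired_inversion_prob = 0.5), "<= 1")
  expect_error(sim_config(conditions = list(c("HBG13"))), "named list")
  expect_error(sim_config(conditions = list(x = "NOPE")), "unknown guide")
})

test_that("edit-probability limits give all-WT and all-edited colonies", {
  cfg0 <- sim_config(per_guide_edit_prob = 0,
                     paired_deletion_prob = 0, paired_inversion_prob = 0,
                     colonies_per_condition = 5, seed = 3)
  sim0 <- simulate_colonies(cfg0)
  expect_true(all(sim0$alleles$edit_type == "WT"))
  dos <- c("hbg_dosage", "bcl11a_series", "zbtb7a_dosage",
           "hbb_hbd", "hbd_3p5kb", "hbb_3p5kb")
  expect_true(all(as.matrix(sim0$colonies[dos]) == 0))

  cfg1 <- sim_config(per_guide_edit_prob = 1,
                     indel_spectrum = c("-13" = 1),
                     conditions = list(HBG13 = "HBG13"),
                     colonies_per_condition = 10, seed = 3)
  sim1 <- simulate_colonies(cfg1)
  expect_true(all(sim1$colonies$hbg_dosage == 4L))
  expect_true(all(sim1$alleles$edited_bases == 13L))
})

test_that("edited-allele fraction converges to the per-allele probability", {
  # 2500 colonies x 4 promoter alleles = 10,000 Bernoulli draws
  cfg <- sim_config(per_guide_edit_prob = 0.7,
                    conditions = list(HBG13 = "HBG13"),
                    colonies_per_condition = 2500, seed = 11)
  sim <- simulate_colonies(cfg)
  n <- nrow(sim$alleles)
  expect_equal(n, 10000L)
  phat <- mean(sim$alleles$edit_type != "WT")
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("simulation is bit-identical under a seed and varies across seeds", {
  cfg <- sim_config(colonies_per_condition = 8, seed = 42)
  a <- simulate_colonies(cfg)
  b <- simulate_colonies(cfg)
  expect_identical(a, b)
  c2 <- simulate_colonies(cfg, seed = 43)
  expect_false(identical(a$colonies, c2$colonies))
})

test_that("noise-free expression equals the fixed-effect prediction", {
  sim <- simulate_colonies(sim_config(colonies_per_condition = 10, seed = 5))
  pm <- phenotype_model(donor_sd = 0, guide_sd = 0, residual_sd = 0)
  expr <- simulate_expression(sim, pm, seed = 1)
  eta <- pm$baseline_hbg_fraction
  for (nm in names(pm$main_effects))
    eta <- eta + pm$main_effects[[nm]] *
      ifelse(is.na(sim$colonies[[nm]]), 0, sim$colonies[[nm]])
  for (nm in names(pm$interaction_effects)) {
    pr <- strsplit(nm, ":", fixed = TRUE)[[1]]
    d1 <- ifelse(is.na(sim$colonies[[pr[1]]]), 0, sim$colonies[[pr[1]]])
    d2 <- ifelse(is.na(sim$colonies[[pr[2]]]), 0, sim$colonies[[pr[2]]])
    eta <- eta + pm$interaction_effects[[nm]] * d1 * d2
  }
  expect_equal(expr$hbg_fraction, pmin(1, pmax(0, eta)), tolerance = 1e-12)
  expect_equal(expr$hbg_fraction + expr$hbb_fraction, rep(1, nrow(expr)))
})

test_that("null phenotype model recovers its baseline at large n", {
  sim <- simulate_colonies(sim_config(
    conditions = list(AAVS1 = "AAVS1"), colonies_per_condition = 4000,
    seed = 9))
  pm <- phenotype_model(baseline_hbg_fraction = 0.2,
                        main_effects = numeric(0) ,
                        interaction_effects = numeric(0),
                        donor_sd = 0, guide_sd = 0, residual_sd = 0.05)
  expr <- simulate_expression(sim, pm, seed = 2)
  expect_lt(abs(mean(expr$hbg_fraction) - 0.2),
            3 * 0.05 / sqrt(nrow(expr)))
})

test_that("a zero interaction coefficient gives a null cell-mean double difference", {
  # empirical interaction contrast over replicates: (y11-y10)-(y01-y00)
  dd <- replicate(200, {
    seed <- sample.int(1e6, 1)
    d <- sim_deletion_study(seed, colonies_per_condition = 40,
                            interaction = 0)
    cm <- with(d, tapply(hbg_fraction,
                         list(hbb_hbd > 0, hbd_3p5kb > 0), mean))
    (cm[2, 2] - cm[2, 1]) - (cm[1, 2] - cm[1, 1])
  })
  expect_lt(abs(mean(dd, na.rm = TRUE)),
            3 * sd(dd, na.rm = TRUE) / sqrt(sum(!is.na(dd))))
})

test_that("missing dosage columns in the phenotype model are a schema error", {
  sim <- simulate_colonies(sim_config(colonies_per_condition = 4))
  pm <- phenotype_model(main_effects = c(not_a_column = 0.1))
  expect_error(simulate_expression(sim, pm), "not_a_column")
})

test_that("interaction records follow the specified proportions", {
  prof <- data.frame(
    condition = "WT", bait_id = "B",
    bait_chrom = "chr11", bait_start = 0L, bait_end = 2000L,
    target_chrom = "chr11", target_start = c(10000L, 20000L),
    target_end = c(11000L, 21000L), prop = c(0.3, 0.7)
  )
  rec <- simulate_interaction_records(prof, total_counts = 10000,
                                      bf_below_20_fraction = 0, seed = 2)
  expect_equal(sum(rec$count), 10000)
  expect_lt(abs(rec$count[1] - 3000), 3 * sqrt(10000 * 0.3 * 0.7))
  # no record below the downstream BF filter
  expect_identical(nrow(filter_significant(rec)), nrow(rec))

  one <- prof[1, ]; one$prop <- 1
  rec1 <- simulate_interaction_records(one, total_counts = 500, seed = 2)
  expect_equal(rec1$count, 500)

  bad <- prof; bad$prop <- c(0.3, 0.3)
  expect_error(simulate_interaction_records(bad), "sum to 1")
})

test_that("promoter-spanning guide combinations are flagged for exclusion", {
  cfg <- sim_config(conditions = list(SPAN = c("HBG13", "HBB_HBD")),
                    colonies_per_condition = 200,
                    whole_region_del_prob = 0.8, seed = 21)
  sim <- simulate_colonies(cfg)
  hit <- sim$colonies$exclude_reason == "whole_region_deletion"
  expect_gt(mean(hit), 0.65)
  expect_lt(mean(hit), 0.95)
  expect_true("hbg_hbb_region" %in% sim$junctions$element)
})
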