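win <- c(100, 113)

edit <- function(type = "indel", start, end, bases,
                 locus = "HBG1_prom") {
  list(locus = locus, edit_type = type, start = start, end = end,
       edited_bases = bases)
}

test_that("promoter disruption follows the >2 bp window rule", {
  # the recurrent 13 bp deletion spans the element
  expect_true(call_promoter_disruption(edit(start = 101, end = 114,
                                            bases = 13), win))
  # 2 bp substitution inside: boundary, rule requires strictly more
  expect_false(call_promoter_disruption(edit("substitution", 105, 107, 2),
                                        win))
  expect_true(call_promoter_disruption(edit("substitution", 105, 108, 3),
                                       win))
  # 5 bp deletion entirely outside the window
  expect_false(call_promoter_disruption(edit(start = 120, end = 125,
                                             bases = 5), win))
  # insertions count only when the insertion point is inside
  expect_true(call_promoter_disruption(edit(start = 105, end = 105,
                                            bases = 4), win))
  expect_false(call_promoter_disruption(edit(start = 99, end = 99,
                                             bases = 4), win))
  expect_false(call_promoter_disruption(edit("WT", NA, NA, 0), win))
  expect_error(call_promoter_disruption(edit(start = 1, end = 5, bases = 4,
                                             locus = "ZBTB7A"), win),
               "HBG promoter")
})

test_that("disruption is monotone in window overlap", {
  # growing a deletion rightward never flips disruptive -> intact
  calls <- vapply(101:120, function(e)
    call_promoter_disruption(edit(start = 100, end = e, bases = e - 100),
                             win), logical(1))
  expect_true(all(diff(as.integer(calls)) >= 0))
})

test_that("dosage counting is exact and permutation invariant", {
  expect_identical(count_hbg_dosage(rep(FALSE, 4)), 0L)
  expect_identical(count_hbg_dosage(c(TRUE, FALSE, FALSE, FALSE)), 1L)
  expect_identical(count_hbg_dosage(rep(TRUE, 4)), 4L)
  calls <- c(TRUE, FALSE, TRUE, FALSE)
  for (i in 1:5) {
    perm <- sample(calls)
    expect_identical(count_hbg_dosage(perm), count_hbg_dosage(calls))
  }
  expect_error(count_hbg_dosage(c(TRUE, FALSE)), "4")
})

test_that("BCL11A coding covers the allelic series and e2 dosage", {
  F2 <- c(FALSE, FALSE)
  expect_identical(code_bcl11a(F2, F2), 0L)
  expect_identical(code_bcl11a(c(TRUE, FALSE), F2), 1L)
  expect_identical(code_bcl11a(F2, c(TRUE, FALSE)), 2L)
  expect_identical(code_bcl11a(c(TRUE, TRUE), F2), 3L)
  expect_identical(code_bcl11a(F2, c(TRUE, TRUE)), 3L)
  # double heterozygote has no slot in the series
  expect_true(is.na(code_bcl11a(c(TRUE, FALSE), c(TRUE, FALSE))))
  expect_identical(code_bcl11a(c(TRUE, TRUE), F2, scheme = "e2_dosage"), 2L)
  expect_identical(code_bcl11a(c(TRUE, FALSE), c(TRUE, FALSE),
                               scheme = "e2_dosage"), 1L)
})

test_that("ZBTB7A coding counts frameshift alleles", {
  expect_identical(code_zbtb7a(c(FALSE, FALSE)), 0L)
  expect_identical(code_zbtb7a(c(TRUE, FALSE)), 1L)
  expect_identical(code_zbtb7a(c(TRUE, TRUE)), 2L)
  expect_error(code_zbtb7a(TRUE), "2")
})

test_that("junction qPCR zygosity logic matches the assay truth table", {
  r <- call_structural(TRUE, FALSE, FALSE)
  expect_identical(r$deletion_dosage, 0L)
  expect_false(r$inversion_flag); expect_false(r$exclude_flag)

  r <- call_structural(TRUE, TRUE, FALSE)
  expect_identical(r$deletion_dosage, 1L)

  r <- call_structural(FALSE, TRUE, FALSE)   # homozygous deletion
  expect_identical(r$deletion_dosage, 2L)

  r <- call_structural(TRUE, FALSE, TRUE)    # inversion heterozygote
  expect_identical(r$deletion_dosage, 0L)
  expect_true(r$inversion_flag)

  r <- call_structural(FALSE, TRUE, TRUE)    # one deleted, one inverted
  expect_identical(r$deletion_dosage, 1L)
  expect_true(r$inversion_flag)

  r <- call_structural(FALSE, FALSE, FALSE)  # uninterpretable
  expect_true(r$exclude_flag)
  expect_match(r$exclude_reason, "no_amplification")

  expect_error(call_structural(NA, TRUE, FALSE), "present")
})

test_that("junction presence respects the Ct cutoff", {
  expect_identical(junction_presence(c(28, 35, 34.9, NA), 35),
                   c(TRUE, FALSE, TRUE, FALSE))
})

test_that("genotyping round-trips the simulator truth table exactly", {
  sim <- simulate_colonies(sim_config(colonies_per_condition = 60,
                                      seed = 77))
  geno <- call_genotypes(sim$alleles, sim$junctions,
                         colony_info = sim$colonies[1:3])
  geno <- geno[match(sim$colonies$colony_id, geno$colony_id), ]
  cols <- c("hbg_dosage", "bcl11a_e2_dosage", "bcl11a_e4_dosage",
            "bcl11a_series", "zbtb7a_dosage", "hbb_hbd", "hbd_3p5kb",
            "hbb_3p5kb", "hbb_hbd_inv", "hbd_3p5kb_inv", "hbb_3p5kb_inv",
            "exclude_flag", "exclude_reason")
  for (cl in cols)
    expect_equal(unname(geno[[cl]]), unname(sim$colonies[[cl]]),
                 info = cl, ignore_attr = TRUE)
})

test_that("colonies with HBG records require exactly four promoter alleles", {
  sim <- simulate_colonies(sim_config(
    conditions = list(HBG13 = "HBG13"), colonies_per_condition = 3))
  broken <- sim$alleles[-1, ]
  expect_error(call_genotypes(broken), "exactly 4")
})
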