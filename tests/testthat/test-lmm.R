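test_that("design construction counts columns and forms products", {
  d <- sim_deletion_study(1, colonies_per_condition = 10, donors = 2)
  dm <- build_design(d, hbg_fraction ~ hbb_hbd * hbd_3p5kb)
  expect_identical(dm$p, 4L)                       # 1 + 2 mains + 1 product
  expect_identical(dm$q, 2L + 4L)                  # 2 donors + 4 guide sets
  expect_equal(unname(dm$X[, "hbb_hbd:hbd_3p5kb"]),
               unname(dm$X[, "hbb_hbd"] * dm$X[, "hbd_3p5kb"]))
  expect_true(all(rowSums(dm$Z[, dm$group_index == 1]) == 1))

  dm2 <- build_design(d, hbg_fraction ~ hbb_hbd * hbd_3p5kb,
                      ref_levels = c(guide_set_id = "AAVS1"))
  expect_identical(dm2$q, 2L + 3L)

  expect_error(build_design(d, hbg_fraction ~ nonexistent), "lacks")
  expect_error(build_design(d[0, ], hbg_fraction ~ hbb_hbd), "non-empty")
  d$flat <- 0
  expect_error(build_design(d, hbg_fraction ~ hbb_hbd + flat),
               "rank deficient")
})

test_that("excluded colonies are dropped from the design", {
  d <- sim_deletion_study(2, colonies_per_condition = 10)
  d$exclude_flag[1:3] <- TRUE
  dm <- build_design(d, hbg_fraction ~ hbb_hbd)
  expect_identical(dm$n, nrow(d) - 3L)
  expect_identical(dm$dropped_excluded, 3L)
})

test_that("zero variance components reduce GLS to ordinary least squares", {
  d <- sim_deletion_study(3, colonies_per_condition = 15)
  dm <- build_design(d, hbg_fraction ~ hbb_hbd * hbd_3p5kb)
  f0 <- fit_reml(dm, lambda = c(0, 0))
  ols <- lm(hbg_fraction ~ hbb_hbd * hbd_3p5kb, d)
  expect_equal(unname(f0$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_true(all(f0$boundary))

  # no random terms at all: the fit is OLS with exact residual df
  fno <- colony_lmm(hbg_fraction ~ hbb_hbd * hbd_3p5kb, d, random = NULL)
  expect_equal(unname(coef(fno)), unname(coef(ols)), tolerance = 1e-10)
  s <- satterthwaite(fno, "hbb_hbd")
  expect_equal(s$df, nrow(d) - 4)
  expect_equal(s$p_value, summary(ols)$coefficients["hbb_hbd", 4],
               tolerance = 1e-10)
})

test_that("balanced one-way REML matches the ANOVA closed forms", {
  k <- 6; m <- 10
  d <- sim_oneway(k, m, seed = 8)
  fit <- colony_lmm(y ~ 1, d, random = ~ group)
  mom <- oneway_anova_components(d, m)
  expect_gt(mom["between"], 0)       # interior case
  expect_equal(unname(fit$fit$varcomp["group"]), unname(mom["between"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$fit$varcomp["residual"]), unname(mom["within"]),
               tolerance = 1e-6)
  # GLS at the estimated components equals the grand mean under balance
  expect_equal(unname(coef(fit)), mean(d$y), tolerance = 1e-8)
  # intercept t-test carries the between-group ANOVA df
  expect_equal(satterthwaite(fit, 1)$df, k - 1, tolerance = 1e-3)
})

test_that("fits agree with the lme4/lmerTest reference implementation", {
  skip_if_not_installed("lmerTest")
  d <- sim_deletion_study(5, colonies_per_condition = 25,
                          interaction = 0.05)
  d <- d[!d$exclude_flag, ]
  fit <- colony_lmm(hbg_fraction ~ hbb_hbd * hbd_3p5kb, d)
  ref <- lmerTest::lmer(
    hbg_fraction ~ hbb_hbd * hbd_3p5kb + (1 | donor_id) +
      (1 | guide_set_id), d)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)),
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(ref))
  ref_vc <- setNames(vc$vcov, vc$grp)
  expect_equal(unname(fit$fit$varcomp[c("donor_id", "guide_set_id",
                                        "residual")]),
               unname(ref_vc[c("donor_id", "guide_set_id", "Residual")]),
               tolerance = 1e-4)
  expect_equal(as.numeric(logLik(fit)), as.numeric(logLik(ref)),
               tolerance = 1e-6)
  mytab <- summary(fit)$coefficients
  reftab <- coef(summary(ref))
  expect_equal(unname(mytab[, "df"]), unname(reftab[, "df"]),
               tolerance = 0.02)
  expect_equal(unname(mytab[, "Pr(>|t|)"]), unname(reftab[, "Pr(>|t|)"]),
               tolerance = 1e-4)
})

test_that("the fit is invariant to row permutation and reproducible", {
  d <- sim_deletion_study(6, colonies_per_condition = 15)
  fit1 <- colony_lmm(hbg_fraction ~ hbb_hbd * hbd_3p5kb, d)
  set.seed(99)
  fit2 <- colony_lmm(hbg_fraction ~ hbb_hbd * hbd_3p5kb,
                     d[sample(nrow(d)), ])
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-8)
  expect_equal(fit1$fit$varcomp, fit2$fit$varcomp, tolerance = 1e-6)
  fit3 <- colony_lmm(hbg_fraction ~ hbb_hbd * hbd_3p5kb, d)
  expect_identical(coef(fit1), coef(fit3))
})

test_that("REML beta estimates are unbiased on simulated data", {
  est <- vapply(1:200, function(i) {
    d <- sim_deletion_study(3000 + i, colonies_per_condition = 25,
                            interaction = 0.05)
    coef(colony_lmm(hbg_fraction ~ hbb_hbd * hbd_3p5kb,
                    d))["hbb_hbd:hbd_3p5kb"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.05), 3 * sd(est) / sqrt(length(est)))
})

test_that("log-transform fits act on the log response", {
  d <- sim_deletion_study(7, colonies_per_condition = 15)
  d <- d[d$hbg_fraction > 0, ]
  fit <- colony_lmm(hbg_fraction ~ hbb_hbd, d, transform = "log",
                    random = NULL)
  ols <- lm(log(hbg_fraction) ~ hbb_hbd, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  d$hbg_fraction[1] <- 0
  expect_error(colony_lmm(hbg_fraction ~ hbb_hbd, d, transform = "log"),
               "positive")
})

test_that("predictions, profiles and parallelism behave algebraically", {
  d <- sim_deletion_study(9, colonies_per_condition = 20,
                          interaction = 0.06)
  fit <- colony_lmm(hbg_fraction ~ hbb_hbd * hbd_3p5kb, d)
  # prediction at the unedited reference is the intercept
  p0 <- predict(fit, data.frame(hbb_hbd = 0, hbd_3p5kb = 0))
  expect_equal(unname(p0), unname(coef(fit)[1]), tolerance = 1e-12)
  expect_warning(predict(fit, data.frame(hbb_hbd = 5, hbd_3p5kb = 0)),
                 "extrapolat")

  prof <- interaction_profile(fit)
  expect_true(all(c("fit", "lwr", "upr") %in% names(prof)))
  expect_true(all(prof$lwr <= prof$fit & prof$fit <= prof$upr))

  # force a zero interaction: profile lines exactly parallel
  fit0 <- fit
  fit0$fit$beta["hbb_hbd:hbd_3p5kb"] <- 0
  pr0 <- interaction_profile(fit0)
  slopes <- vapply(split(pr0, pr0$hbd_3p5kb),
                   function(x) diff(range(x$fit)), numeric(1))
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)

  # positive interaction: slope in factor 1 increases with factor 2
  fitp <- fit
  fitp$fit$beta["hbb_hbd:hbd_3p5kb"] <- 0.1
  prp <- interaction_profile(fitp)
  sl <- vapply(split(prp, prp$hbd_3p5kb), function(x)
    coef(lm(fit ~ hbb_hbd, x))[2], numeric(1))
  expect_true(all(diff(sl) > 0))

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  out <- plot(fit)
  expect_s3_class(out, "data.frame")
})

test_that("simulate, residuals and ranef are coherent", {
  d <- sim_deletion_study(10, colonies_per_condition = 15)
  fit <- colony_lmm(hbg_fraction ~ hbb_hbd * hbd_3p5kb, d)
  ys <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(ys), c(fit$dm$n, 3L))
  expect_equal(residuals(fit, "marginal"),
               fit$dm$y - drop(fit$dm$X %*% coef(fit)), tolerance = 1e-12)
  expect_equal(fitted(fit) + residuals(fit), fit$dm$y, tolerance = 1e-12,
               ignore_attr = TRUE)
  re <- ranef(fit)
  expect_named(re, c("donor_id", "guide_set_id"), ignore.order = TRUE)
  # BLUPs shrink toward zero relative to raw group residuals
  expect_lt(max(abs(re$donor_id)), max(abs(tapply(
    residuals(fit, "marginal"), fit$dm$data$donor_id, mean))) + 1e-9)
})

test_that("confidence intervals cover the Wald construction", {
  d <- sim_deletion_study(11, colonies_per_condition = 15)
  fit <- colony_lmm(hbg_fraction ~ hbb_hbd, d)
  ci <- confint(fit)
  s <- satterthwaite(fit, "hbb_hbd")
  expect_equal(unname(ci["hbb_hbd", ]),
               s$estimate + c(-1, 1) * qt(0.975, s$df) * s$se,
               tolerance = 1e-10)
})
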