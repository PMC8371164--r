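# shared fixtures built in code

# small two-deletion study used by the model tests; interaction truth
# is given by `interaction`, everything else held at study defaults
sim_deletion_study <- function(seed, colonies_per_condition = 30L,
                               donors = 4L, interaction = 0,
                               clip = TRUE) {
  cfg <- sim_config(
    donors = donors,
    colonies_per_condition = colonies_per_condition,
    conditions = list(AAVS1 = "AAVS1", HBB_HBD = "HBB_HBD",
                      HBD_3p5kb = "HBD_3p5kb",
                      BOTH = c("HBB_HBD", "HBD_3p5kb")),
    seed = seed
  )
  pm <- phenotype_model(
    main_effects = c(hbb_hbd = 0.12, hbd_3p5kb = 0.08),
    interaction_effects = c("hbb_hbd:hbd_3p5kb" = interaction),
    donor_sd = 0.03, guide_sd = 0.03, residual_sd = 0.08
  )
  # one RNG stream per replicate study
  set.seed(seed)
  sim <- simulate_colonies(cfg, seed = NULL)
  expr <- simulate_expression(sim, pm, seed = NULL, clip = clip)
  merge(sim$colonies, expr, by = "colony_id", sort = FALSE)
}

# balanced one-way random-intercept data: k groups of m, group sd taub,
# residual sd sige
sim_oneway <- function(k, m, mu = 1, taub = 0.3, sige = 0.5, seed = 1) {
  set.seed(seed)
  g <- rep(sprintf("G%02d", seq_len(k)), each = m)
  y <- mu + rep(rnorm(k, 0, taub), each = m) + rnorm(k * m, 0, sige)
  data.frame(y = y, group = g)
}

# method-of-moments / ANOVA closed forms for the balanced one-way
# design, which coincide with REML when the between estimate is interior
oneway_anova_components <- function(d, m) {
  gm <- tapply(d$y, d$group, mean)
  k <- length(gm)
  msw <- sum((d$y - gm[d$group])^2) / (k * (m - 1))
  msb <- m * sum((gm - mean(gm))^2) / (k - 1)
  c(between = (msb - msw) / m, within = msw)
}
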