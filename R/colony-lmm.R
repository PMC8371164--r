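#' Fit a dosage interaction linear mixed model to colony data
#'
#' The central model of the package: globin expression in single edited
#' erythroid colonies regressed on ordinal genotype dosages, their
#' pairwise products (the genetic-interaction terms of interest), and
#' random intercepts for cell donor and for the guide set delivered, with
#' variance components estimated by REML and fixed-effect inference by
#' Satterthwaite-approximate t-tests. A positive interaction coefficient
#' on the HBG fraction indicates synergy between two perturbations
#' (reinforcing derepression of the fetal genes); a negative one
#' indicates antagonism (overlapping pathways); zero gives parallel
#' interaction-profile lines.
#'
#' @param formula Model formula; dosage variables are numeric, so
#'   `hbg_fraction ~ hbb_hbd * hbd_3p5kb` expands to intercept, two main
#'   dosages and their product.
#' @param data Merged colony table (genotypes + expression); rows with
#'   `exclude_flag == TRUE` are dropped.
#' @param random One-sided formula of grouping factors for independent
#'   random intercepts (default donor and guide set); `NULL` for ordinary
#'   least squares.
#' @param transform `"identity"` (default; response modeled on its own
#'   scale) or `"log"`.
#' @param ref_levels Optional named character vector giving, per grouping
#'   variable, a reference level with no indicator column (e.g.
#'   `c(guide_set_id = "AAVS1")` so the unperturbed control defines the
#'   basal level).
#' @return An object of class `"colony_lmm"` with `print`, `summary`,
#'   `coef`, `vcov`, `confint`, `predict`, `plot`, `simulate`,
#'   `residuals`, `fitted`, `ranef` and `logLik` methods.
#' @examples
#' sim <- simulate_colonies(sim_config(colonies_per_condition = 20))
#' expr <- simulate_expression(sim, seed = 7)
#' d <- merge(sim$colonies, expr, by = "colony_id")
#' fit <- colony_lmm(hbg_fraction ~ hbb_hbd * hbd_3p5kb, d)
#' summary(fit)
#' @export
colony_lmm <- function(formula, data, random = ~ donor_id + guide_set_id,
                       transform = c("identity", "log"),
                       ref_levels = NULL) {
  transform <- match.arg(transform)
  cl <- match.call()
  dm <- build_design(data, formula, random = random,
                     ref_levels = ref_levels, transform = transform)
  fit <- fit_reml(dm)
  structure(list(fit = fit, dm = dm, formula = formula, random = random,
                 transform = transform, call = cl),
            class = "colony_lmm")
}

#' Preset model formulas of the colony study
#'
#' The three fixed-effect structures used to interrogate genetic
#' interactions: `"dd_interaction"` crosses the two partial beta-globin
#' locus deletions (HBB-HBD and HBD-3.5kb); `"bcl11a_hbg"` combines the
#' HBB-3.5kb deletion and the HBG1/2 promoter dosage with the BCL11A
#' allelic series and their interactions; `"bcl11a_zbtb7a"` combines the
#' HBB-3.5kb deletion and ZBTB7A dosage with the BCL11A series and their
#' interactions.
#'
#' @param model Preset name.
#' @param response Response column, typically `"hbg_fraction"` or
#'   `"hbb_fraction"`.
#' @return A model formula for [colony_lmm()].
#' @export
model_formula <- function(model = c("dd_interaction", "bcl11a_hbg",
                                    "bcl11a_zbtb7a"),
                          response = "hbg_fraction") {
  model <- match.arg(model)
  rhs <- switch(model,
    dd_interaction = "hbb_hbd * hbd_3p5kb",
    bcl11a_hbg = paste("hbb_3p5kb + hbg_dosage + bcl11a_series +",
                       "hbb_3p5kb:bcl11a_series +",
                       "hbg_dosage:bcl11a_series"),
    bcl11a_zbtb7a = paste("hbb_3p5kb + zbtb7a_dosage + bcl11a_series +",
                          "hbb_3p5kb:zbtb7a_dosage +",
                          "bcl11a_series:zbtb7a_dosage"))
  stats::as.formula(paste(response, "~", rhs), env = globalenv())
}

#' Restrict a colony table to the conditions informative for a model
#'
#' Each interaction model is fit to the experimental arms that perturb
#' its dosage variables, plus the unperturbed control arm. A condition is
#' kept when at least one of its colonies carries a non-zero dosage for
#' some model variable, or when it is the control.
#'
#' @param data Merged colony table.
#' @param formula Model formula whose right-hand-side variables define
#'   relevance.
#' @param control Name(s) of control guide-set conditions always kept.
#' @return The subsetted data.frame.
#' @export
model_subset <- function(data, formula, control = "AAVS1") {
  vars <- intersect(all.vars(formula[[3]]), names(data))
  if (!length(vars)) return(data)
  keep_lv <- vapply(split(data[vars], data$guide_set_id),
                    function(d) any(d > 0, na.rm = TRUE), TRUE)
  keep <- data$guide_set_id %in% c(names(keep_lv)[keep_lv], control)
  data[keep, , drop = FALSE]
}

#' @export
print.colony_lmm <- function(x, digits = 4, ...) {
  cat("Colony interaction linear mixed model (REML)\n")
  cat("  formula: ", deparse(x$formula), "\n")
  if (length(x$dm$group_names))
    cat("  random intercepts:", paste(x$dm$group_names, collapse = ", "),
        "\n")
  cat("  n =", x$dm$n, "colonies")
  if (x$dm$dropped_excluded)
    cat(" (", x$dm$dropped_excluded, "excluded)")
  cat("\n\nFixed effects:\n")
  print(round(coef(x), digits))
  cat("\nVariance components (sd):\n")
  print(round(sqrt(x$fit$varcomp), digits))
  invisible(x)
}

#' @export
coef.colony_lmm <- function(object, ...) object$fit$beta

#' @export
vcov.colony_lmm <- function(object, ...) object$fit$cov_beta

#' @export
logLik.colony_lmm <- function(object, ...) {
  structure(object$fit$reml_loglik,
            df = object$dm$p + length(object$fit$varcomp),
            nobs = object$dm$n, class = "logLik")
}

#' Summarize a colony mixed-model fit
#'
#' Produces the coefficient table with standard errors, Satterthwaite
#' degrees of freedom, t statistics and two-sided p-values, plus variance
#' components.
#'
#' @param object A `colony_lmm` fit.
#' @param ... Unused.
#' @export
summary.colony_lmm <- function(object, ...) {
  p <- object$dm$p
  tab <- t(vapply(seq_len(p), function(j) {
    s <- satterthwaite(object$fit, j)
    c(Estimate = s$estimate, `Std. Error` = s$se, df = s$df,
      `t value` = s$statistic, `Pr(>|t|)` = s$p_value)
  }, numeric(5)))
  rownames(tab) <- names(object$fit$beta)
  out <- list(coefficients = tab, varcomp = object$fit$varcomp,
              reml_loglik = object$fit$reml_loglik,
              n = object$dm$n, formula = object$formula,
              group_names = object$dm$group_names,
              boundary = object$fit$boundary,
              dropped = object$dm$dropped_excluded)
  class(out) <- "summary.colony_lmm"
  out
}

#' @export
print.summary.colony_lmm <- function(x, digits = 4, ...) {
  cat("Colony interaction linear mixed model (REML)\n")
  cat("  formula: ", deparse(x$formula), "\n")
  cat("  n =", x$n, "  REML logLik =", round(x$reml_loglik, 2), "\n\n")
  cat("Fixed effects (Satterthwaite df):\n")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat("\nVariance components:\n")
  vc <- data.frame(variance = x$varcomp, sd = sqrt(x$varcomp))
  print(round(vc, 6))
  if (any(x$boundary))
    cat("note: variance component(s) at the zero boundary:",
        paste(x$group_names[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' @export
confint.colony_lmm <- function(object, parm, level = 0.95, ...) {
  beta <- object$fit$beta
  nm <- names(beta)
  if (missing(parm)) parm <- nm
  if (is.numeric(parm)) parm <- nm[parm]
  out <- t(vapply(parm, function(j) {
    s <- satterthwaite(object$fit, j)
    s$estimate + c(-1, 1) * qt(1 - (1 - level) / 2, s$df) * s$se
  }, numeric(2)))
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' Predict population-level expression for dosage combinations
#'
#' Fixed-effects predictions `x0' beta`, optionally with confidence
#' intervals from the fixed-effect covariance using Satterthwaite t
#' quantiles. Dosage values outside the observed range trigger an
#' extrapolation warning.
#'
#' @param object A `colony_lmm` fit.
#' @param newdata Data.frame of dosage combinations; defaults to the
#'   fitted data.
#' @param interval `"none"` or `"confidence"`.
#' @param level Confidence level.
#' @param ... Unused.
#' @return Numeric vector, or data.frame `fit`, `lwr`, `upr`.
#' @export
predict.colony_lmm <- function(object, newdata = NULL,
                               interval = c("none", "confidence"),
                               level = 0.95, ...) {
  interval <- match.arg(interval)
  trm <- delete.response(object$dm$terms)
  if (is.null(newdata)) {
    X0 <- object$dm$X
  } else {
    for (v in all.vars(trm)) {
      obs <- object$dm$fixed_frame[[v]]
      if (is.numeric(obs) && v %in% names(newdata) &&
          (any(newdata[[v]] < min(obs)) || any(newdata[[v]] > max(obs))))
        warning("extrapolating beyond the observed range of ", v)
    }
    mf0 <- model.frame(trm, newdata, xlev = attr(object$dm, "xlevels"))
    X0 <- model.matrix(trm, mf0)
  }
  est <- drop(X0 %*% object$fit$beta)
  if (interval == "none") return(est)
  lwr <- upr <- numeric(length(est))
  for (i in seq_along(est)) {
    s <- satterthwaite(object$fit, X0[i, ])
    qv <- qt(1 - (1 - level) / 2, s$df) * s$se
    lwr[i] <- est[i] - qv; upr[i] <- est[i] + qv
  }
  data.frame(fit = est, lwr = lwr, upr = upr)
}

#' @export
fitted.colony_lmm <- function(object, ...) {
  drop(object$dm$X %*% object$fit$beta) +
    if (object$dm$q) drop(object$dm$Z %*% .blup(object)) else 0
}

#' @export
residuals.colony_lmm <- function(object,
                                 type = c("conditional", "marginal"),
                                 ...) {
  type <- match.arg(type)
  r <- object$dm$y - drop(object$dm$X %*% object$fit$beta)
  if (type == "conditional" && object$dm$q)
    r <- r - drop(object$dm$Z %*% .blup(object))
  r
}

# BLUPs of the random intercepts: u = Lambda Z' V0^{-1} (y - X beta)
.blup <- function(object) {
  dm <- object$dm; fit <- object$fit
  if (!dm$q) return(numeric(0))
  lam_col <- fit$lambda[dm$group_index]
  r <- dm$y - drop(dm$X %*% fit$beta)
  s <- sqrt(lam_col)
  M <- crossprod(dm$Z) * outer(s, s)
  diag(M) <- diag(M) + 1
  Ztr <- drop(crossprod(dm$Z, r))
  v0inv_part <- Ztr - crossprod(dm$Z) %*% (s * solve(M, s * Ztr))
  drop(lam_col * v0inv_part)
}

#' Extract random-intercept BLUPs
#'
#' @param object A `colony_lmm` fit.
#' @return Named list, one numeric vector of conditional means per
#'   grouping factor.
#' @export
ranef <- function(object) {
  stopifnot(inherits(object, "colony_lmm"))
  u <- .blup(object)
  names(u) <- colnames(object$dm$Z)
  split(u, object$dm$group_names[object$dm$group_index])
}

#' @export
simulate.colony_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dm <- object$dm; fit <- object$fit
  mu <- drop(dm$X %*% fit$beta)
  out <- replicate(nsim, {
    y <- mu + rnorm(dm$n, 0, sqrt(fit$sigma2))
    if (dm$q) {
      u <- rnorm(dm$q, 0, sqrt(fit$sigma2 * fit$lambda[dm$group_index]))
      y <- y + drop(dm$Z %*% u)
    }
    y
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
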