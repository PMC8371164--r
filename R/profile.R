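#' Interaction profile: predicted means over a dosage grid
#'
#' Evaluates the fitted fixed-effect surface over all combinations of two
#' dosage variables (every other model variable held at 0, the unedited
#' reference), with 95% confidence bands from the fixed-effect
#' covariance. When the interaction coefficient is zero the profile lines
#' across the second variable are exactly parallel; a positive
#' interaction makes the slope in the first variable increase with the
#' second (synergy), a negative one makes it decrease (antagonism).
#'
#' @param object A [colony_lmm()] fit.
#' @param vars Character vector of the two interacting dosage variables;
#'   defaults to the first product term in the model.
#' @param grid Optional data.frame of combinations to evaluate; defaults
#'   to the Cartesian product of the observed dosage values.
#' @param level Confidence level for the bands.
#' @return Data.frame: the two dosage variables, `fit`, `lwr`, `upr`.
#' @export
interaction_profile <- function(object, vars = NULL, grid = NULL,
                                level = 0.95) {
  stopifnot(inherits(object, "colony_lmm"))
  labs <- attr(object$dm$terms, "term.labels")
  if (is.null(vars)) {
    prod_terms <- labs[grepl(":", labs, fixed = TRUE)]
    if (!length(prod_terms))
      stop("model has no interaction term; supply `vars`", call. = FALSE)
    vars <- strsplit(prod_terms[1], ":", fixed = TRUE)[[1]]
  }
  stopifnot(length(vars) == 2)
  mf <- object$dm$fixed_frame
  num_vars <- setdiff(all.vars(delete.response(object$dm$terms)), vars)
  if (is.null(grid)) {
    grid <- expand.grid(sort(unique(mf[[vars[1]]])),
                        sort(unique(mf[[vars[2]]])))
    names(grid) <- vars
  }
  for (v in num_vars) grid[[v]] <- 0
  pr <- predict(object, newdata = grid, interval = "confidence",
                level = level)
  out <- cbind(grid[vars], pr)
  rownames(out) <- NULL
  out
}

#' Plot the interaction profile of a colony mixed-model fit
#'
#' Draws predicted expression against the first interacting dosage, one
#' line (with a shaded 95% confidence band) per level of the second
#' dosage. Non-parallel lines are the visual signature of a genetic
#' interaction.
#'
#' @param x A [colony_lmm()] fit.
#' @param vars,grid,level Passed to [interaction_profile()].
#' @param xlab,ylab,main Axis and title labels.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.colony_lmm <- function(x, vars = NULL, grid = NULL, level = 0.95,
                            xlab = NULL, ylab = NULL, main = NULL, ...) {
  prof <- interaction_profile(x, vars = vars, grid = grid, level = level)
  v1 <- names(prof)[1]; v2 <- names(prof)[2]
  lv2 <- sort(unique(prof[[v2]]))
  cols <- grDevices::hcl.colors(max(3, length(lv2)), "Dark 3")
  plot(range(prof[[v1]]), range(c(prof$lwr, prof$upr)), type = "n",
       xlab = if (is.null(xlab)) paste(v1, "dosage") else xlab,
       ylab = if (is.null(ylab)) deparse(x$formula[[2]]) else ylab,
       main = if (is.null(main)) "Interaction profile" else main, ...)
  for (i in seq_along(lv2)) {
    pi <- prof[prof[[v2]] == lv2[i], ]
    pi <- pi[order(pi[[v1]]), ]
    polygon(c(pi[[v1]], rev(pi[[v1]])), c(pi$lwr, rev(pi$upr)),
            col = grDevices::adjustcolor(cols[i], alpha.f = 0.2),
            border = NA)
    lines(pi[[v1]], pi$fit, col = cols[i], lwd = 2)
    points(pi[[v1]], pi$fit, col = cols[i], pch = 16)
  }
  legend("topleft", legend = paste(v2, "=", lv2), col = cols[seq_along(lv2)],
         lwd = 2, bty = "n", cex = 0.8)
  invisible(prof)
}
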