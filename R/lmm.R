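#' Build mixed-model design matrices from a colony table
#'
#' Constructs the response vector, fixed-effect matrix and random-intercept
#' indicator matrix for a dosage interaction model. Fixed effects come from
#' a standard model formula (dosage variables are numeric, so `a * b`
#' yields intercept, mains and the elementwise product column). Each term
#' of the one-sided `random` formula contributes one indicator column per
#' level of that grouping factor; a level named in `ref_levels` (e.g. the
#' unperturbed control condition, whose basal level is absorbed by the
#' intercept) contributes no column. Rows flagged for exclusion are
#' dropped and counted.
#'
#' @param data Colony data.frame (merged genotypes + expression).
#' @param formula Model formula, e.g.
#'   `hbg_fraction ~ hbb_hbd * hbd_3p5kb`.
#' @param random One-sided formula of grouping variables, e.g.
#'   `~ donor_id + guide_set_id`, or `NULL` for a fixed-effects-only
#'   model.
#' @param ref_levels Optional named character vector mapping a grouping
#'   variable to a reference level that gets no indicator column.
#' @param transform `"identity"` or `"log"` applied to the response.
#' @param drop_excluded Drop rows with `exclude_flag == TRUE`.
#' @return List of class `"colony_design"`: `y`, `X`, `Z`, `group_index`
#'   (grouping factor per Z column), `group_names`, `n`, `p`, `q`,
#'   `terms`, plus bookkeeping for prediction.
#' @export
build_design <- function(data, formula, random = ~ donor_id + guide_set_id,
                         ref_levels = NULL,
                         transform = c("identity", "log"),
                         drop_excluded = TRUE) {
  transform <- match.arg(transform)
  if (!is.data.frame(data) || nrow(data) == 0)
    stop("`data` must be a non-empty data.frame", call. = FALSE)
  vars <- all.vars(formula)
  rvars <- if (!is.null(random)) all.vars(random) else character()
  miss <- setdiff(c(vars, rvars), names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  dropped <- 0L
  if (drop_excluded && "exclude_flag" %in% names(data)) {
    dropped <- sum(data$exclude_flag, na.rm = TRUE)
    data <- data[!data$exclude_flag %in% TRUE, , drop = FALSE]
  }
  keep <- stats::complete.cases(data[, c(vars, rvars), drop = FALSE])
  dropped_na <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) stop("no usable rows after exclusions", call. = FALSE)

  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (transform == "log") {
    if (any(y <= 0))
      stop("log transform requires a strictly positive response (",
           sum(y <= 0), " non-positive values)", call. = FALSE)
    y <- log(y)
  }
  trm <- terms(mf)
  X <- model.matrix(trm, mf)
  if (qr(X)$rank < ncol(X)) {
    const <- names(which(apply(X[, -1, drop = FALSE], 2,
                               function(v) var(v) == 0)))
    stop("fixed-effect matrix is rank deficient",
         if (length(const)) paste0(" (constant column(s): ",
                                   paste(const, collapse = ", "), ")"),
         call. = FALSE)
  }

  group_names <- rvars
  Zs <- list(); gi <- integer()
  for (k in seq_along(group_names)) {
    g <- factor(data[[group_names[k]]])
    cols <- levels(g)
    ref <- if (group_names[k] %in% names(ref_levels))
      ref_levels[[group_names[k]]] else NULL
    if (!is.null(ref)) cols <- setdiff(cols, ref)
    Zk <- matrix(0, nrow(data), length(cols),
                 dimnames = list(NULL, paste(group_names[k], cols,
                                             sep = ":")))
    m <- match(as.character(g), cols)
    ok <- !is.na(m)
    Zk[cbind(which(ok), m[ok])] <- 1
    Zs[[k]] <- Zk
    gi <- c(gi, rep(k, length(cols)))
  }
  Z <- if (length(Zs)) do.call(cbind, Zs) else
    matrix(0, nrow(data), 0)

  structure(list(
    y = as.numeric(y), X = X, Z = Z, group_index = gi,
    group_names = group_names, n = nrow(X), p = ncol(X), q = ncol(Z),
    terms = trm, transform = transform,
    fixed_frame = mf, data = data,
    dropped_excluded = dropped, dropped_incomplete = dropped_na
  ), class = "colony_design")
}

# sufficient statistics reused across optimizer iterations
.design_stats <- function(dm) {
  list(XtX = crossprod(dm$X), XtZ = crossprod(dm$X, dm$Z),
       Xty = crossprod(dm$X, dm$y), ZtZ = crossprod(dm$Z),
       Zty = crossprod(dm$Z, dm$y), yty = sum(dm$y^2),
       n = dm$n, p = dm$p, q = dm$q, gi = dm$group_index,
       K = length(dm$group_names))
}

# profiled REML pieces at variance ratios lambda (one per grouping).
# V0 = I + Z diag(lambda[gi]) Z'; everything via the q x q capacitance
# matrix so each evaluation is O(q^3 + p^3).
.reml_parts <- function(lambda, st) {
  lam_col <- if (st$q) pmax(lambda[st$gi], 0) else numeric(0)
  s <- sqrt(lam_col)
  if (st$q) {
    M <- st$ZtZ * outer(s, s)
    diag(M) <- diag(M) + 1
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    logdetV0 <- 2 * sum(log(diag(R)))
    G <- forwardsolve(t(R), t(st$XtZ) * s)          # q x p
    gv <- forwardsolve(t(R), st$Zty * s)            # q x 1
    A_xx <- st$XtX - crossprod(G)
    a_xy <- st$Xty - crossprod(G, gv)
    yVy <- st$yty - sum(gv^2)
  } else {
    logdetV0 <- 0
    A_xx <- st$XtX; a_xy <- st$Xty; yVy <- st$yty
  }
  Rx <- tryCatch(chol(A_xx), error = function(e) NULL)
  if (is.null(Rx)) return(NULL)
  logdetA <- 2 * sum(log(diag(Rx)))
  u <- forwardsolve(t(Rx), a_xy)
  beta <- backsolve(Rx, u)
  yPy <- max(yVy - sum(u^2), 1e-300)
  list(logdetV0 = logdetV0, logdetA = logdetA, yPy = yPy,
       beta = drop(beta), Rx = Rx, A_xx = A_xx)
}

.reml_crit <- function(loglam, st) {
  parts <- .reml_parts(exp(pmin(loglam, 25)), st)
  if (is.null(parts)) return(1e10)
  np <- st$n - st$p
  sigma2 <- parts$yPy / np
  np * (log(2 * pi) + log(sigma2) + 1) + parts$logdetV0 + parts$logdetA
}

# -2 REML log-likelihood on the natural variance scale
# theta = (sigma2_1, ..., sigma2_K, sigma2_resid)
.m2lR_theta <- function(theta, st) {
  K <- st$K
  s2e <- theta[K + 1]
  if (s2e <= 0) return(1e10)
  lam <- if (K) pmax(theta[seq_len(K)], 0) / s2e else numeric(0)
  parts <- .reml_parts(lam, st)
  if (is.null(parts)) return(1e10)
  np <- st$n - st$p
  np * log(2 * pi) + np * log(s2e) + parts$logdetV0 + parts$logdetA +
    parts$yPy / s2e
}

#' Fit the dosage interaction mixed model by REML
#'
#' Maximizes the restricted likelihood of `y = X beta + Z u + e` over the
#' variance ratios `lambda_k = sigma2_k / sigma2_e` (one per grouping
#' factor, log-parameterized so non-negativity is automatic), profiling
#' out `beta` and the residual variance. The optimizer is Nelder-Mead
#' from a fixed set of starting values, so the fit is deterministic for
#' given data. Variance-component estimates that collapse to the boundary
#' (zero) are flagged, not errors. With no random terms the fit is
#' ordinary least squares.
#'
#' @param dm A design from [build_design()].
#' @param lambda Optional fixed variance ratios (length = number of
#'   grouping factors) to skip optimization, e.g. `c(0, 0)` for the
#'   zero-variance (GLS = OLS) limit.
#' @return List of class `"reml_fit"`: `beta`, `cov_beta`, `sigma2`
#'   (residual variance), `varcomp` (named variance components incl.
#'   `residual`), `lambda`, `reml_loglik`, `boundary`, `converged`,
#'   `n_iter`.
#' @export
fit_reml <- function(dm, lambda = NULL) {
  stopifnot(inherits(dm, "colony_design"))
  if (dm$n <= dm$p)
    stop("need more observations than fixed-effect columns (n = ", dm$n,
         ", p = ", dm$p, ")", call. = FALSE)
  st <- .design_stats(dm)
  K <- st$K
  n_iter <- 0L; converged <- TRUE

  if (K == 0L) {
    lam_hat <- numeric(0)
  } else if (!is.null(lambda)) {
    stopifnot(length(lambda) == K, all(lambda >= 0))
    lam_hat <- lambda
  } else {
    starts <- list(rep(0, K), rep(-3, K), rep(2, K))
    best <- NULL
    for (s0 in starts) {
      opt <- if (K == 1L)
        optim(s0, .reml_crit, st = st, method = "Brent",
              lower = -30, upper = 25,
              control = list(maxit = 2000, reltol = 1e-12))
      else
        optim(s0, .reml_crit, st = st, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
      n_iter <- n_iter + if (is.na(opt$counts[1])) 1L else opt$counts[1]
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (best$convergence != 0) {
      converged <- FALSE
      warning("REML optimizer did not fully converge (code ",
              best$convergence, " after ", n_iter, " evaluations)")
    }
    # high-precision polish of the simplex solution; a line-search abort
    # at this tolerance is expected and the better value is kept
    pol <- tryCatch(
      optim(best$par, .reml_crit, st = st, method = "L-BFGS-B",
            lower = -30, upper = 25,
            control = list(factr = 1, maxit = 200)),
      error = function(e) best)
    if (pol$value <= best$value) best <- pol
    lam_hat <- exp(pmin(best$par, 25))
  }

  parts <- .reml_parts(lam_hat, st)
  if (is.null(parts)) stop("REML evaluation failed at the optimum",
                           call. = FALSE)
  np <- st$n - st$p
  sigma2 <- parts$yPy / np
  crit <- np * (log(2 * pi) + log(sigma2) + 1) + parts$logdetV0 +
    parts$logdetA
  cov_beta <- sigma2 * chol2inv(parts$Rx)
  dimnames(cov_beta) <- list(colnames(dm$X), colnames(dm$X))
  boundary <- K > 0 & lam_hat < 1e-6
  varcomp <- c(if (K) setNames(sigma2 * lam_hat, dm$group_names),
               residual = sigma2)
  structure(list(
    beta = setNames(parts$beta, colnames(dm$X)), cov_beta = cov_beta,
    sigma2 = sigma2, varcomp = varcomp, lambda = lam_hat,
    reml_loglik = -0.5 * crit, boundary = boundary,
    converged = converged, n_iter = n_iter, st = st
  ), class = "reml_fit")
}

# central-difference gradient and Hessian
.fd_grad <- function(f, x, h) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h[i])
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

.fd_hess <- function(f, x, h) {
  m <- length(x)
  H <- matrix(NA_real_, m, m)
  f0 <- f(x)
  for (i in seq_len(m)) {
    ei <- replace(numeric(m), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < m) for (j in (i + 1):m) {
      ej <- replace(numeric(m), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Satterthwaite approximate inference for a fixed-effect contrast
#'
#' Computes the effective degrees of freedom
#' `df = 2 Var(c'b)^2 / (g' A g)`, where `g` is the gradient of
#' `Var(c'b)` with respect to the variance components and `A` their
#' asymptotic covariance (twice the inverse finite-difference Hessian of
#' the -2 REML log-likelihood), and the corresponding t-test p-value.
#' With no random components the exact residual degrees of freedom
#' `n - p` are used. Variance components at the zero boundary are held
#' fixed; if the variance-component information is singular the residual
#' df are used with a warning.
#'
#' @param fit A [fit_reml()] result (or a `colony_lmm` fit).
#' @param contrast Numeric contrast vector of length p, or the name or
#'   index of a single coefficient.
#' @return List: `estimate`, `se`, `df`, `statistic`, `p_value`.
#' @export
satterthwaite <- function(fit, contrast) {
  if (inherits(fit, "colony_lmm")) fit <- fit$fit
  stopifnot(inherits(fit, "reml_fit"))
  st <- fit$st
  p <- st$p; K <- st$K
  if (is.character(contrast) || (length(contrast) == 1 && contrast == round(contrast) && length(fit$beta) > 1)) {
    idx <- if (is.character(contrast)) match(contrast, names(fit$beta))
           else as.integer(contrast)
    if (is.na(idx) || idx < 1 || idx > p)
      stop("unknown coefficient: ", contrast, call. = FALSE)
    contrast <- replace(numeric(p), idx, 1)
  }
  stopifnot(length(contrast) == p)
  est <- sum(contrast * fit$beta)
  v0 <- drop(t(contrast) %*% fit$cov_beta %*% contrast)
  se <- sqrt(v0)

  resid_df <- st$n - p
  if (K == 0L) {
    stat <- est / se
    return(list(estimate = est, se = se, df = resid_df, statistic = stat,
                p_value = 2 * pt(-abs(stat), resid_df)))
  }

  theta <- c(fit$varcomp[seq_len(K)], fit$varcomp[["residual"]])
  free <- c(theta[seq_len(K)] > 1e-6 * fit$sigma2, TRUE)
  var_c <- function(th_free) {
    th <- theta
    th[free] <- th_free
    s2e <- th[K + 1]
    lam <- pmax(th[seq_len(K)], 0) / s2e
    parts <- .reml_parts(lam, st)
    if (is.null(parts)) return(NA_real_)
    s2e * drop(t(contrast) %*% chol2inv(parts$Rx) %*% contrast)
  }
  m2l <- function(th_free) {
    th <- theta
    th[free] <- th_free
    .m2lR_theta(th, st)
  }
  th_free <- theta[free]
  h <- pmax(1e-4 * abs(th_free), 1e-7 * fit$sigma2)
  # keep proposals away from negative variances
  h <- pmin(h, pmax(th_free / 2, 1e-12))
  df <- tryCatch({
    H <- .fd_hess(m2l, th_free, h)
    A <- 2 * solve(H)
    g <- .fd_grad(var_c, th_free, h)
    denom <- drop(t(g) %*% A %*% g)
    if (!is.finite(denom) || denom <= 0) stop("singular information")
    2 * v0^2 / denom
  }, error = function(e) {
    warning("variance-component information singular; ",
            "falling back to residual df")
    resid_df
  })
  if (!is.finite(df) || df <= 0) df <- resid_df
  stat <- est / se
  list(estimate = est, se = se, df = df, statistic = stat,
       p_value = 2 * pt(-abs(stat), df))
}
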