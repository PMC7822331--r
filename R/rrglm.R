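# Value, gradient and Hessian of the randomized-response logistic
# log-likelihood at beta. Rows carry their own misclassification pair
# (cc, dd); mu is clipped away from 0/1 so boundary rows with c = 0 or
# c + d = 1 keep finite terms.
rr_ll_parts <- function(beta, X, y, cc, dd, eps = 1e-12) {
  eta <- drop(X %*% beta)
  mu <- clip_unit(stats::plogis(eta), eps)
  lam <- cc + dd * mu
  val <- sum(y * log(lam) + (1 - y) * log1p(-lam))
  m <- mu * (1 - mu)
  v <- lam * (1 - lam)
  r <- (y - lam) / v
  A <- r * dd * m
  grad <- drop(crossprod(X, A))
  rprime <- -dd * m * (v + (y - lam) * (1 - 2 * lam)) / v^2
  dA <- dd * (m * (1 - 2 * mu) * r + m * rprime)
  H <- crossprod(X, X * dA)
  list(value = val, gradient = grad, hessian = H, mu = mu, lambda = lam)
}

#' Log-likelihood of the randomized-response logistic model
#'
#' For respondent i with covariates \eqn{x_i}, misclassification pair
#' \eqn{(c_i, d_i)} and latent success probability
#' \eqn{\mu_i = logit^{-1}(x_i^T\beta)}, the observed answer is Bernoulli
#' with probability \eqn{\lambda_i = c_i + d_i \mu_i}, giving
#' \deqn{\ell(\beta) = \sum_i y_i \log\lambda_i + (1-y_i)\log(1-\lambda_i).}
#' With all \eqn{(c_i, d_i) = (0, 1)} this is the ordinary Bernoulli-logit
#' log-likelihood.
#'
#' @param beta Coefficient vector.
#' @param X Numeric model matrix (including intercept column).
#' @param y Observed 0/1 answers.
#' @param c,d Per-row misclassification parameters (scalars recycled); each
#'   row must satisfy \eqn{0 \le c_i}, \eqn{c_i + d_i \le 1}, \eqn{d_i > 0}.
#' @return List with `value` (log-likelihood) and `gradient` (analytic).
#' @export
rr_loglik <- function(beta, X, y, c, d) {
  X <- as.matrix(X)
  n <- nrow(X)
  cc <- rep_len(c, n); dd <- rep_len(d, n)
  if (any(cc < 0) || any(cc + dd > 1 + 1e-12) || any(dd <= 0))
    stop_invalid("misclassification pairs must satisfy 0 <= c, c + d <= 1, d > 0")
  if (length(beta) != ncol(X)) stop_invalid("`beta` length must match ncol(X)")
  p <- rr_ll_parts(beta, X, y, cc, dd)
  list(value = p$value, gradient = p$gradient)
}

rr_glm_control <- function(maxit = 100L, grad_tol = 1e-8, eps = 1e-12) {
  list(maxit = maxit, grad_tol = grad_tol, eps = eps)
}

# Resolve the per-row (c, d) matrix from a design specification: a single
# rr_design, or a named list of designs indexed by an arm column.
resolve_cd <- function(design, data, arm, n) {
  if (is_rr_design(design))
    return(cbind(c = rep(design$c, n), d = rep(design$d, n)))
  if (is.list(design) && all(vapply(design, is_rr_design, logical(1)))) {
    if (is.null(arm))
      stop_invalid("a list of designs needs `arm` naming the arm column")
    lab <- as.character(data[[arm]])
    bad <- setdiff(unique(lab), names(design))
    if (length(bad))
      stop_invalid("no design supplied for arm level(s): ",
                   paste(bad, collapse = ", "))
    return(cbind(c = vapply(design, `[[`, 0, "c")[lab],
                 d = vapply(design, `[[`, 0, "d")[lab]))
  }
  stop_invalid("`design` must be an rr_design or a named list of them")
}

#' Logistic regression for randomized binary responses
#'
#' Fits by maximum likelihood the logistic model for a latent sensitive
#' status observed through a (possibly respondent-specific) randomization
#' device: the latent probability is \eqn{\mu_i = logit^{-1}(x_i^T\beta)}
#' and the observed answer is Bernoulli\eqn{(c_i + d_i\mu_i)}. Rows from a
#' direct-questioning arm carry \eqn{(c, d) = (0, 1)}, rows from a
#' forced-response arm the device's line (e.g. (0.2, 0.6) for the 40-card
#' deck), so both arms enter one joint fit, with the questioning method
#' typically also present as a covariate capturing residual reporting
#' differences.
#'
#' Optimization is Newton's method with step-halving from \eqn{\beta = 0},
#' falling back to BFGS when the Hessian is not negative definite. Standard
#' errors come from the inverse observed information at the optimum; Wald
#' z statistics and two-sided normal p-values are reported per coefficient,
#' along with exp(beta) odds ratios and the AIC.
#'
#' @param formula Model formula for the latent status (e.g.
#'   `resp_theft ~ arm + crime + oc_score`).
#' @param data Data frame containing the response and covariates.
#' @param design An [rr_design()] applying to all rows, or a named list of
#'   designs (e.g. `list(direct = direct_design(), indirect =
#'   deck_design(8, 8, 24))`) indexed by the `arm` column.
#' @param arm Name of the column holding arm labels when `design` is a
#'   list; default `"arm"`.
#' @param start Optional starting coefficients (default all zero).
#' @param control List from `rr_glm_control()`: `maxit`, `grad_tol`
#'   (max-norm of the gradient at convergence, default 1e-8), `eps`
#'   (probability clipping).
#' @return An object of class `rrglm`; see [summary.rrglm()],
#'   [pearson_gof()], [odds_ratio_table()], [step_rr_glm()].
#' @examples
#' svy <- simulate_survey(cohort_config(n = 400, seed = 7))
#' fit <- rr_glm(resp_theft ~ arm + oc_score, svy,
#'               design = list(direct = direct_design(),
#'                             indirect = deck_design(8, 8, 24)))
#' summary(fit)
#' @export
rr_glm <- function(formula, data, design, arm = "arm", start = NULL,
                   control = rr_glm_control()) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_invalid("the response must be 0/1 with no missing values")
  y <- as.numeric(y)
  X <- stats::model.matrix(mt, mf)
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop_invalid("more parameters (", k, ") than observations (", n, ")")
  qrX <- qr(X)
  if (qrX$rank < k) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop_invalid("model matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", "))
  }
  cd <- resolve_cd(design, data, arm, nrow(data))
  # align cd with model-frame rows (model.frame may drop rows only on NA,
  # which we forbid, but subset defensively by row names)
  keep <- match(rownames(mf), rownames(data))
  if (!anyNA(keep)) cd <- cd[keep, , drop = FALSE]
  cc <- cd[, "c"]; dd <- cd[, "d"]
  if (any(cc < 0) || any(cc + dd > 1 + 1e-12) || any(dd <= 0))
    stop_invalid("invalid per-row misclassification parameters")

  beta <- start %||% rep(0, k)
  parts <- rr_ll_parts(beta, X, y, cc, dd, control$eps)
  converged <- FALSE
  used_fallback <- FALSE
  iter <- 0L
  while (iter < control$maxit) {
    if (max(abs(parts$gradient)) < control$grad_tol) { converged <- TRUE; break }
    iter <- iter + 1L
    negH <- -parts$hessian
    ch <- tryCatch(chol(negH), error = function(e) NULL)
    if (is.null(ch)) { used_fallback <- TRUE; break }
    step <- backsolve(ch, forwardsolve(t(ch), parts$gradient))
    t_ls <- 1
    repeat {
      cand <- beta + t_ls * step
      cand_parts <- rr_ll_parts(cand, X, y, cc, dd, control$eps)
      if (cand_parts$value >= parts$value || t_ls < 1e-10) break
      t_ls <- t_ls / 2
    }
    if (cand_parts$value < parts$value) { used_fallback <- TRUE; break }
    beta <- cand
    parts <- cand_parts
  }
  if (!converged && used_fallback) {
    # quasi-Newton rescue for non-concave regions
    opt <- stats::optim(beta, fn = function(b) -rr_ll_parts(b, X, y, cc, dd,
                                                            control$eps)$value,
                        gr = function(b) -rr_ll_parts(b, X, y, cc, dd,
                                                      control$eps)$gradient,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    beta <- opt$par
    parts <- rr_ll_parts(beta, X, y, cc, dd, control$eps)
    iter <- iter + opt$counts[["function"]]
    converged <- max(abs(parts$gradient)) < max(control$grad_tol, 1e-6)
  }
  if (!converged && max(abs(parts$gradient)) < control$grad_tol)
    converged <- TRUE

  vc <- tryCatch(solve(-parts$hessian), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) <= 0)) {
    vc <- matrix(NA_real_, k, k)
    converged <- FALSE
  }
  se <- sqrt(diag(vc))
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  wald_z <- beta / se
  fit <- structure(
    list(coefficients = beta, se = se, vcov = vc,
         wald_z = wald_z, wald_p = 2 * stats::pnorm(-abs(wald_z)),
         odds_ratio = exp(beta),
         loglik = parts$value, aic = 2 * k - 2 * parts$value,
         n = n, k = k, df.residual = n - k,
         converged = converged, iterations = iter,
         fitted_mu = unname(parts$mu), fitted_lambda = unname(parts$lambda),
         y = y, X = X, cd = cd,
         formula = formula, terms = mt, xlevels = stats::.getXlevels(mt, mf),
         design = design, arm = arm, call = cl, control = control),
    class = "rrglm"
  )
  fit
}

#' Pearson goodness-of-fit statistic of a randomized-response fit
#'
#' \deqn{X^2 = \sum_i (y_i - \lambda_i^*)^2 / (\lambda_i^*(1-\lambda_i^*))}
#' with fitted observed-response probabilities
#' \eqn{\lambda_i^* = c_i + d_i\hat\mu_i}, referred to a chi-square with
#' n - k degrees of freedom. With ungrouped binary data the chi-square
#' reference is approximate (the statistic's variance depends on the
#' \eqn{\lambda_i^*}); fitted probabilities within 1e-12 of 0 or 1 are
#' clipped and reported.
#'
#' @param fit An [rr_glm()] fit.
#' @return An object of class `htest` with the statistic, degrees of
#'   freedom and p-value.
#' @export
pearson_gof <- function(fit) {
  if (!inherits(fit, "rrglm")) stop_invalid("`fit` must be an rrglm object")
  if (!fit$converged) warning("fit did not converge; statistic unreliable",
                              call. = FALSE)
  p <- fit$fitted_lambda
  n_clip <- sum(p < 1e-12 | p > 1 - 1e-12)
  if (n_clip > 0)
    message(n_clip, " fitted probabilit",
            if (n_clip > 1) "ies" else "y", " clipped away from 0/1")
  p <- clip_unit(p, 1e-12)
  x2 <- sum((fit$y - p)^2 / (p * (1 - p)))
  df <- fit$df.residual
  structure(
    list(statistic = c("X-squared" = x2), parameter = c(df = df),
         p.value = stats::pchisq(x2, df, lower.tail = FALSE),
         method = "Pearson goodness-of-fit test for a randomized-response logistic model",
         data.name = deparse(fit$formula)),
    class = "htest"
  )
}

#' Coefficient and odds-ratio report of a randomized-response fit
#'
#' One row per model term: estimate, standard error, exp(estimate) (the
#' odds-ratio column of the usual report), and the two-sided Wald p-value.
#' The print method formats to 4 decimals and lists the reference class of
#' every categorical term.
#'
#' @param fit An [rr_glm()] fit.
#' @return Data frame of class `rr_or_table`.
#' @export
odds_ratio_table <- function(fit) {
  if (!inherits(fit, "rrglm")) stop_invalid("`fit` must be an rrglm object")
  out <- data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    std_error = unname(fit$se),
                    odds_ratio = unname(fit$odds_ratio),
                    p_value = unname(fit$wald_p),
                    stringsAsFactors = FALSE)
  attr(out, "reference_classes") <-
    vapply(fit$xlevels, `[`, character(1), 1L)
  class(out) <- c("rr_or_table", "data.frame")
  out
}

#' @export
print.rr_or_table <- function(x, digits = 4, ...) {
  disp <- data.frame(term = x$term,
                     estimate = fmt_num(x$estimate, digits),
                     std_error = fmt_num(x$std_error, digits),
                     odds_ratio = fmt_num(x$odds_ratio, digits),
                     p_value = ifelse(x$p_value < 0.001, "<0.001",
                                      fmt_num(x$p_value, digits)))
  print.data.frame(disp, row.names = FALSE)
  rc <- attr(x, "reference_classes")
  if (length(rc))
    cat("Reference classes:",
        paste(names(rc), rc, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
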