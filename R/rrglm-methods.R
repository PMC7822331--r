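#' @export
print.rrglm <- function(x, digits = 4, ...) {
  cat("Randomized-response logistic regression\n")
  cat("Call: ", paste(deparse(x$call), collapse = "\n"), "\n\n", sep = "")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nn = %d, parameters = %d, logLik = %.3f, AIC = %.2f\n",
              x$n, x$k, x$loglik, x$aic))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
coef.rrglm <- function(object, ...) object$coefficients

#' @export
vcov.rrglm <- function(object, ...) object$vcov

#' @export
logLik.rrglm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Summarize a randomized-response logistic fit
#'
#' Coefficient table with standard errors, Wald z statistics, two-sided
#' p-values and odds ratios, followed by the AIC and the Pearson
#' goodness-of-fit p-value.
#'
#' @param object An [rr_glm()] fit.
#' @param ... Unused.
#' @return An object of class `summary.rrglm`.
#' @export
summary.rrglm <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. error` = object$se,
               `z value` = object$wald_z,
               `Pr(>|z|)` = object$wald_p,
               `Exp(estimate)` = object$odds_ratio)
  gof <- suppressMessages(suppressWarnings(pearson_gof(object)))
  structure(list(call = object$call, coefficients = tab,
                 aic = object$aic, loglik = object$loglik,
                 pearson = gof, n = object$n, k = object$k,
                 converged = object$converged,
                 iterations = object$iterations,
                 xlevels = object$xlevels),
            class = "summary.rrglm")
}

#' @export
print.summary.rrglm <- function(x, digits = 4, ...) {
  cat("Randomized-response logistic regression\n")
  cat("Call: ", paste(deparse(x$call), collapse = "\n"), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE, cs.ind = 1:2, tst.ind = 3,
                      zap.ind = 5)
  if (length(x$xlevels))
    cat("Reference classes:",
        paste(names(x$xlevels),
              vapply(x$xlevels, `[`, character(1), 1L),
              sep = " = ", collapse = ", "), "\n")
  cat(sprintf("\nAIC %.2f   logLik %.3f   n %d   parameters %d\n",
              x$aic, x$loglik, x$n, x$k))
  cat(sprintf("Pearson X^2 = %.3f on %d df, p = %.4g\n",
              x$pearson$statistic, x$pearson$parameter, x$pearson$p.value))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' Predict from a randomized-response logistic fit
#'
#' @param object An [rr_glm()] fit.
#' @param newdata Optional data frame; defaults to the fitted data.
#' @param type `"latent"` for the latent success probability
#'   \eqn{\mu = logit^{-1}(x^T\beta)}, `"response"` for the observed-answer
#'   probability \eqn{\lambda = c + d\mu}, `"link"` for the linear
#'   predictor.
#' @param design,arm Misclassification specification for `newdata`;
#'   defaults to the one used in fitting.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rrglm <- function(object, newdata = NULL,
                          type = c("latent", "response", "link"),
                          design = NULL, arm = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(switch(type,
                  latent = object$fitted_mu,
                  response = object$fitted_lambda,
                  link = stats::qlogis(object$fitted_mu)))
  }
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") return(eta)
  mu <- stats::plogis(eta)
  if (type == "latent") return(mu)
  cd <- resolve_cd(design %||% object$design, newdata,
                   arm %||% object$arm, nrow(newdata))
  drop(cd[, "c"] + cd[, "d"] * mu)
}

#' @export
residuals.rrglm <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  p <- clip_unit(object$fitted_lambda, 1e-12)
  r <- object$y - p
  if (type == "pearson") r <- r / sqrt(p * (1 - p))
  r
}

#' Simulate observed answers from a fitted randomized-response model
#'
#' Draws new 0/1 answers from the fitted observed-response probabilities
#' \eqn{\lambda_i^*} (latent status passed through each row's device).
#'
#' @param object An [rr_glm()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.rrglm <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$fitted_lambda
  with_seed(seed, {
    out <- as.data.frame(
      matrix(stats::rbinom(length(p) * nsim, 1L, rep(p, nsim)),
             ncol = nsim,
             dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
    out
  })
}
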