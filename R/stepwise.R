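# Refit an rrglm with a new formula in the environment of the original call.
refit_rrglm <- function(object, formula, env = parent.frame()) {
  cl <- object$call
  cl$formula <- formula
  eval(cl, env)
}

#' Bidirectional AIC stepwise selection for randomized-response models
#'
#' Starting from a fitted model, repeatedly evaluates all single-term
#' removals (and additions from `scope`), moves to the candidate with the
#' lowest AIC, and stops at a local minimum. Categorical terms enter and
#' leave as whole blocks (a term is a column of the terms object, so a
#' factor's dummies move together). Terms named in `keep` are never
#' removed; by default any term called `arm` or `method` is protected,
#' since the questioning method is the design variable of interest in this
#' class of models.
#'
#' @param object An [rr_glm()] fit (the full model to start from).
#' @param scope Character vector of additional candidate terms that may be
#'   added; default none (backward-dominant selection).
#' @param keep Character vector of term labels never dropped.
#' @param trace Logical; print each accepted move.
#' @param steps Maximum number of moves.
#' @return The selected [rr_glm()] fit, with attribute `"path"` recording
#'   the accepted moves and AIC values.
#' @export
step_rr_glm <- function(object, scope = character(),
                        keep = intersect(c("arm", "method", "Method"),
                                         attr(object$terms, "term.labels")),
                        trace = FALSE, steps = 50L) {
  if (!inherits(object, "rrglm")) stop_invalid("`object` must be an rrglm fit")
  env <- environment(object$formula) %||% parent.frame()
  current <- object
  path <- data.frame(step = 0L, move = "<start>", aic = object$aic,
                     stringsAsFactors = FALSE)
  for (s in seq_len(steps)) {
    terms_now <- attr(current$terms, "term.labels")
    droppable <- setdiff(terms_now, keep)
    addable <- setdiff(scope, terms_now)
    moves <- c(if (length(droppable)) paste("-", droppable),
               if (length(addable)) paste("+", addable))
    if (!length(moves)) break
    fits <- lapply(moves, function(mv) {
      op <- substr(mv, 1, 1)
      term <- substring(mv, 3)
      new_terms <- if (op == "-") setdiff(terms_now, term)
                   else c(terms_now, term)
      rhs <- if (length(new_terms)) paste(new_terms, collapse = " + ") else "1"
      f <- stats::reformulate(rhs, response = object$formula[[2]])
      tryCatch(refit_rrglm(current, f, env), error = function(e) NULL)
    })
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, 0)
    best <- which.min(aics)
    if (aics[best] >= current$aic - 1e-8) break
    current <- fits[[best]]
    path <- rbind(path, data.frame(step = s, move = moves[best],
                                   aic = current$aic))
    if (trace)
      cat(sprintf("step %d: %s  AIC %.3f\n", s, moves[best], current$aic))
  }
  attr(current, "path") <- path
  current
}
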