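#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`, then
#' restores the previous RNG state, so seeded draws inside package functions
#' never perturb the caller's random stream. A `NULL` seed evaluates `code`
#' against the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically spawn `n` sub-seeds from one master seed, so pipeline
# stages draw from independent substreams and adding a stage does not perturb
# the draws of earlier ones. NULLs are returned when no master seed is given
# (stages then share the caller's stream).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  as.list(with_seed(seed, sample.int(2147483646L, n)))
}

clip_unit <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

# Fixed-decimal formatting used by all written reports (4 decimals by
# default, the convention of the estimate tables).
fmt_num <- function(x, digits = 4) {
  out <- formatC(x, format = "f", digits = digits)
  out[is.na(x)] <- "NA"
  out
}

stop_invalid <- function(...) stop(..., call. = FALSE)
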