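#' @importFrom stats approx approxfun dbinom lm median optim quantile rbinom
#'   rexp rnorm runif sd setNames var coef resid predict
#' @importFrom utils head tail modifyList
#' @importFrom data.table := data.table as.data.table copy rbindlist setDT
#'   setnames set fread fwrite setorder .N .SD
NULL

# quiet R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  "error_at_reappear", "response", "correct", "trial_id", "confidence",
  "t_start", "t_end", "class", "visibility", "amplitude_deg",
  "mean_speed_dps", "phase", "radius", "phase_diff", "radius_diff",
  "euclidean", "participant_id", "t_launch", "t_land", "J"
))

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards. With `seed = NULL` the expression is evaluated with
#' the ambient RNG state (no isolation).
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific child seed from a user seed; stays well below 2^31.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stream) %% 1000L
}

stopifnot_named <- function(x, fields, what) {
  miss <- setdiff(fields, names(x))
  if (length(miss))
    stop(sprintf("%s is missing fields: %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
}
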