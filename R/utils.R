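## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

## Stable 31-bit polynomial hash of a string; used to fan a global seed out to
## per-stage child seeds so stages rerun standalone reproduce the composed run.
stable_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647L
  as.integer(h)
}

#' Derive a per-stage child seed from a global seed
#'
#' Child seeds are a deterministic function of the global seed and the stage
#' name, so a stage rerun in isolation draws the same random stream as in the
#' composed pipeline run.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  as.integer((as.numeric(seed) %% 2147483647 + stable_hash(stage)) %% 2147483647)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop_param("`%s` must be a single positive finite number", name)
  invisible(x)
}

## Range helper for synthetic shape parameters: c(min, max) with max >= min.
check_range <- function(r, name, lower = -Inf) {
  if (!is.numeric(r) || length(r) != 2 || any(!is.finite(r)))
    stop_param("`%s` must be a numeric range c(min, max)", name)
  if (r[2] < r[1])
    stop_param("`%s` is degenerate: max (%g) < min (%g)", name, r[2], r[1])
  if (r[1] < lower)
    stop_param("`%s` lower bound must be >= %g", name, lower)
  invisible(r)
}

runif_range <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

sample_int_range <- function(r) {
  if (r[1] == r[2]) return(as.integer(r[1]))
  sample(seq.int(as.integer(r[1]), as.integer(r[2])), 1)
}
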