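# Internal helpers shared across the package.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's random stream.
#' @noRd
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a child seed from a parent seed and a stage tag
#'
#' Deterministic, stays below 2^31 so the result is a valid R integer seed.
#' @noRd
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483587)
}

stop_lpc <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# positive scalar check
chk_scalar <- function(x, name, lower = -Inf, upper = Inf,
                       strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_lpc(sprintf("'%s' must be a finite numeric scalar", name))
  }
  if (strict_lower && x <= lower) stop_lpc(sprintf("'%s' must be > %g", name, lower))
  if (!strict_lower && x < lower) stop_lpc(sprintf("'%s' must be >= %g", name, lower))
  if (strict_upper && x >= upper) stop_lpc(sprintf("'%s' must be < %g", name, upper))
  if (!strict_upper && x > upper) stop_lpc(sprintf("'%s' must be <= %g", name, upper))
  invisible(x)
}
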