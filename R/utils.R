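# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the global RNG, runs `code`, and restores the previous RNG state so
#' that seeded package functions do not disturb the caller's random stream.
#' A `NULL` seed leaves the current stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed; keeps results < 2^31 so they remain
# valid R integer seeds.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1103L + as.double(k) * 12345L) %% 2147483647)
}

stop_domain <- function(...) {
  stop(structure(class = c("replicascan_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("replicascan_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

fmt_pct <- function(x) formatC(x, format = "f", digits = 2)
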