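# Internal helpers shared across modules.

#' @keywords internal
#' @importFrom methods is
#' @importFrom stats predict coef
#' @importFrom utils head
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream. seed = NULL evaluates expr unchanged.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Round half away from zero (printed-table convention); base round() is
# round-half-even which disagrees on exact .xx5 boundaries.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_netstrat <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "netstrat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Deterministic fan-out of a master seed into per-stage seeds, kept well
# below .Machine$integer.max.
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + as.integer(stage) * 7919L) %% 2147483629L
}

is_binary_matrix <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}
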