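# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-decimal rounding with ties going up (half-up), the convention used
#' for all displayed percentages. Base `round()` rounds half to even, which
#' disagrees with printed QC tables at exact .005 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(99.975, 2)  # 99.98, where round() gives 99.97 or 99.98
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All package randomness flows through this.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.double(seed) * 11L + offset * 7919) %% 2147483647
}

stop_if_not_fraction <- function(x, name, closed_right = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    (if (closed_right) x <= 1 else x < 1)
  if (!ok) stop(sprintf("`%s` must be a fraction in [0,1], got %s",
                        name, deparse(substitute(x))), call. = FALSE)
  invisible(x)
}
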