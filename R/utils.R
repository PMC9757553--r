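#' Standard gravity used for body-weight normalisation
#'
#' Conversion constant between mass and body weight: 9.80665 m/s^2.
#' @export
GRAVITY <- 9.80665

# Stop with the offending argument named, for scalar validation.
check_finite_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("parameter '%s' must be a finite numeric scalar", name),
         call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("parameter '%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Run an expression with a local, restorable RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a parent seed and an index; stays below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

# Linear interpolation helper returning 0 outside the input range.
interp_zero <- function(x, y, xout) {
  out <- stats::approx(x, y, xout = xout, rule = 1)$y
  out[is.na(out)] <- 0
  out
}
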