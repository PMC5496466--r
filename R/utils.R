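`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# `seed = NULL` uses (and advances) the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Moore-Penrose pseudo-inverse by SVD with a relative singular-value cutoff.
# Returns the minimum-norm inverse; rank deficiency is reported via the
# "rank" and "condition" attributes so callers can warn.
pseudo_inverse <- function(X, rtol = 1e-10) {
  X <- as.matrix(X)
  s <- svd(X)
  if (length(s$d) == 0L || s$d[1] <= 0) {
    out <- matrix(0, ncol(X), nrow(X))
    attr(out, "rank") <- 0L
    attr(out, "condition") <- Inf
    return(out)
  }
  keep <- s$d > rtol * s$d[1]
  out <- s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  attr(out, "rank") <- sum(keep)
  attr(out, "condition") <- s$d[1] / min(s$d[keep])
  out
}

# Derive a stream of independent sub-seeds from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_scalar_number <- function(x, name, positive = TRUE,
                                      integerish = FALSE, zero_ok = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  }
  if (positive && !(x > 0 || (zero_ok && x == 0))) {
    stop(sprintf("'%s' must be %s", name,
                 if (zero_ok) "non-negative" else "positive"), call. = FALSE)
  }
  invisible(x)
}
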