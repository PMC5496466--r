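#' Wavelet transform specification
#'
#' Describes the orthonormal discrete wavelet transform used for denoising:
#' the Daubechies family member, the number of decomposition levels, and how
#' series whose length is not a multiple of `2^levels` are extended before
#' the (circular) transform is applied.
#'
#' The transform itself is the periodized orthonormal filter bank, so on
#' conforming lengths coefficient energy equals signal energy and the
#' transform inverts exactly. Non-conforming lengths (e.g. 124 scans after
#' discarding 4 of 128) are first extended to the next admissible length --
#' by reflecting the tail (`boundary = "symmetric"`, a dialect choice that
#' avoids the wrap-around jump of periodic extension) or by wrapping the head
#' (`boundary = "periodic"`) -- transformed, and truncated after inversion.
#'
#' @param family `"d4"` (4-tap Daubechies, the default), `"haar"`, `"d6"` or
#'   `"d8"`.
#' @param levels decomposition depth; `NULL` (default) uses the maximum depth
#'   admissible for the (extended) length.
#' @param boundary extension rule for non-conforming lengths.
#' @return Object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(family = c("d4", "haar", "d6", "d8"),
                         levels = NULL,
                         boundary = c("symmetric", "periodic")) {
  family <- match.arg(family)
  boundary <- match.arg(boundary)
  if (!is.null(levels)) {
    stop_if_not_scalar_number(levels, "levels", integerish = TRUE)
    levels <- as.integer(levels)
  }
  structure(list(family = family, levels = levels, boundary = boundary),
            class = "wavelet_spec")
}

# Orthonormal Daubechies scaling (lowpass) filters, sum h = sqrt(2),
# sum h^2 = 1. d4 is exact in closed form; d6/d8 are the standard
# minimum-phase coefficient tables.
wavelet_filters <- function(family) {
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    d4 = {
      s3 <- sqrt(3)
      c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
    },
    d6 = c(0.33267055295095688, 0.80689150931333875, 0.45987750211933132,
           -0.13501102001039084, -0.08544127388224149, 0.03522629188210562),
    d8 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
           -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
           0.03288301166698295, -0.01059740178499728),
    stop("unknown wavelet family: ", family, call. = FALSE)
  )
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h) # quadrature mirror highpass
  list(h = h, g = g, length = L)
}

# Depth admissible for length n: each split needs the current length even
# and at least the filter support (keeps every periodized step orthogonal).
max_dwt_levels <- function(n, flen) {
  J <- 0L
  m <- n
  while (m %% 2L == 0L && m >= flen && m >= 2L) {
    J <- J + 1L
    m <- m %/% 2L
  }
  J
}

# One analysis level on a matrix (series in rows, m columns, m even):
# a_k = sum_j h_j x_{(2k+j) mod m}, d_k likewise with g.
.dwt_step <- function(X, h, g) {
  m <- ncol(X)
  ks <- seq(0L, m - 2L, by = 2L)
  A <- matrix(0, nrow(X), m %/% 2L)
  D <- matrix(0, nrow(X), m %/% 2L)
  for (j in seq_along(h)) {
    cols <- ((ks + (j - 1L)) %% m) + 1L
    Xj <- X[, cols, drop = FALSE]
    A <- A + h[j] * Xj
    D <- D + g[j] * Xj
  }
  list(A = A, D = D)
}

# Transposed (synthesis) level: x_{(2k+j) mod m} += h_j a_k + g_j d_k.
.idwt_step <- function(A, D, h, g) {
  m <- 2L * ncol(A)
  ks <- seq(0L, m - 2L, by = 2L)
  X <- matrix(0, nrow(A), m)
  for (j in seq_along(h)) {
    cols <- ((ks + (j - 1L)) %% m) + 1L
    X[, cols] <- X[, cols] + h[j] * A + g[j] * D
  }
  X
}

# Extend rows of X to length n_target per the boundary rule.
.extend_matrix <- function(X, n_target, boundary) {
  n0 <- ncol(X)
  pad <- n_target - n0
  if (pad == 0L) return(X)
  if (pad > n0) {
    stop(sprintf("series of length %d is too short to extend to %d", n0, n_target),
         call. = FALSE)
  }
  ext <- if (boundary == "symmetric") {
    X[, n0:(n0 - pad + 1L), drop = FALSE] # reflect the tail
  } else {
    X[, seq_len(pad), drop = FALSE]       # wrap the head
  }
  cbind(X, ext)
}

# Full forward transform on a matrix; returns the coefficient matrix with
# columns ordered (approx_J | detail_J | ... | detail_1) plus layout info.
.dwt_forward_matrix <- function(X, spec) {
  filt <- wavelet_filters(spec$family)
  n0 <- ncol(X)
  if (n0 < filt$length) {
    stop(sprintf("series length %d is shorter than the %s filter support (%d)",
                 n0, spec$family, filt$length), call. = FALSE)
  }
  if (any(!is.finite(X))) stop("series must be finite-valued", call. = FALSE)
  if (is.null(spec$levels)) {
    n <- 2^ceiling(log2(n0)) # next dyadic length, full-depth default
  } else {
    step <- 2^spec$levels
    n <- as.integer(ceiling(n0 / step) * step)
  }
  X <- .extend_matrix(X, n, spec$boundary)
  J <- max_dwt_levels(n, filt$length)
  if (!is.null(spec$levels)) J <- min(J, spec$levels)
  if (J < 1L) {
    stop(sprintf("no admissible decomposition level for length %d with family %s",
                 n, spec$family), call. = FALSE)
  }
  details <- vector("list", J)
  A <- X
  for (lev in seq_len(J)) {
    st <- .dwt_step(A, filt$h, filt$g)
    A <- st$A
    details[[lev]] <- st$D
  }
  C <- do.call(cbind, c(list(A), rev(details)))
  list(coefficients = C,
       n = n, orig_length = n0, levels = J,
       approx_length = ncol(A),
       detail_lengths = rev(vapply(details, ncol, integer(1))), # coarse -> fine
       spec = spec)
}

.dwt_inverse_matrix <- function(C, layout) {
  filt <- wavelet_filters(layout$spec$family)
  A <- C[, seq_len(layout$approx_length), drop = FALSE]
  off <- layout$approx_length
  for (lev in seq_along(layout$detail_lengths)) { # coarse -> fine
    dl <- layout$detail_lengths[lev]
    D <- C[, off + seq_len(dl), drop = FALSE]
    A <- .idwt_step(A, D, filt$h, filt$g)
    off <- off + dl
  }
  A[, seq_len(layout$orig_length), drop = FALSE]
}

#' Forward discrete wavelet transform of one series
#'
#' Orthonormal periodized DWT. On lengths that conform to the decomposition
#' depth the transform preserves energy to machine precision and inverts
#' exactly; other lengths are extended per the spec's boundary rule and the
#' inverse truncates back.
#'
#' @param series numeric vector.
#' @param spec a [wavelet_spec()].
#' @return Object of class `wavelet_decomposition` with fields
#'   `coefficients` (ordered approx-coarse-to-fine-details), `n` (number of
#'   coefficients, i.e. the extended length), `orig_length`, `levels`,
#'   `approx_length`, `detail_lengths`, `spec`.
#' @seealso [dwt_inverse()]
#' @export
#' @examples
#' y <- sin(seq(0, 4 * pi, length.out = 64))
#' d <- dwt_forward(y, wavelet_spec())
#' all.equal(sum(d$coefficients^2), sum(y^2))
#' all.equal(dwt_inverse(d), y)
dwt_forward <- function(series, spec = wavelet_spec()) {
  stopifnot(is.numeric(series), inherits(spec, "wavelet_spec"))
  out <- .dwt_forward_matrix(matrix(series, nrow = 1L), spec)
  out$coefficients <- as.numeric(out$coefficients)
  class(out) <- "wavelet_decomposition"
  out
}

#' Inverse discrete wavelet transform
#'
#' @param decomp a `wavelet_decomposition`, optionally with modified
#'   coefficients.
#' @param coefficients replacement coefficient vector (same length/ordering
#'   as `decomp$coefficients`); defaults to the stored ones.
#' @return Numeric vector of length `decomp$orig_length`.
#' @export
dwt_inverse <- function(decomp, coefficients = decomp$coefficients) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  if (length(coefficients) != decomp$n) {
    stop("'coefficients' must match the decomposition length", call. = FALSE)
  }
  as.numeric(.dwt_inverse_matrix(matrix(coefficients, nrow = 1L), decomp))
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("Wavelet decomposition: %s, %d level(s), %d coefficients (series length %d)\n",
              x$spec$family, x$levels, x$n, x$orig_length))
  invisible(x)
}
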