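# Coefficients of a decomposition, or a plain numeric vector.
as_coefficients <- function(x) {
  if (inherits(x, "wavelet_decomposition")) x$coefficients else as.numeric(x)
}

#' Admissible upper bound of the MDL model-order search
#'
#' The retained-coefficient count `k` is searched over `1 <= k < 0.95 n`
#' (strict, so an integral `0.95 n` is excluded) and never reaches `k = n`.
#'
#' @param n number of coefficients.
#' @return Largest admissible `k`.
#' @export
mdl_kmax <- function(n) {
  km <- as.integer(floor(0.95 * n + 1e-9))
  if (abs(km - 0.95 * n) < 1e-9) km <- km - 1L # strict bound
  min(km, n - 1L)
}

# Cost of retaining the k largest-magnitude coefficients, for all k at once.
# s2desc: squared coefficients sorted descending. Degenerate log arguments
# (zero retained or zero residual energy) map to -Inf so argmin stays total.
.mdl_cost_curve <- function(s2desc, criterion) {
  n <- length(s2desc)
  kmax <- mdl_kmax(n)
  k <- seq_len(kmax)
  Sg <- cumsum(s2desc)[k]
  S <- sum(s2desc)
  resid <- S - Sg
  cost <- if (criterion == "cmdl") {
    ((n - k) / 2) * log(resid / (n - k)) +
      (k / 2) * log(Sg / k) +
      0.5 * log(k * (n - k))
  } else {
    ((n - k) / 2) * log(resid / (n - k)^3) +
      (k / 2) * log(Sg / k^3)
  }
  cost[resid <= 0 | Sg <= 0] <- -Inf
  names(cost) <- k
  cost
}

mdl_criterion <- function(criterion) {
  match.arg(criterion, c("rmdl", "cmdl"))
}

#' Crude-MDL cost of retaining the k largest wavelet coefficients
#'
#' Evaluates `((n-k)/2) log((S - S_g)/(n-k)) + (k/2) log(S_g/k) +
#' (1/2) log(k (n-k))`, where `S` is the total squared-coefficient energy and
#' `S_g` the energy of the `k` largest-magnitude coefficients. Degenerate
#' energies (zero residual or zero retained energy) return `-Inf` by
#' convention.
#'
#' @param decomp a `wavelet_decomposition` or a numeric coefficient vector.
#' @param k number of retained coefficients, `1 <= k <= mdl_kmax(n)`.
#' @return The cost (scalar).
#' @export
#' @examples
#' cmdl_cost(c(4, 2, 1, 1, 0.5, 0.5, 0.25, 0.25), k = 2) # ~1.065
cmdl_cost <- function(decomp, k) {
  .mdl_cost_at(decomp, k, "cmdl")
}

#' Refined-MDL cost of retaining the k largest wavelet coefficients
#'
#' Evaluates `((n-k)/2) log((S - S_g)/(n-k)^3) + (k/2) log(S_g/k^3)`; the
#' refinement charges for encoding the class index, penalising model orders
#' more strongly than the crude cost. Degenerate energies return `-Inf`.
#'
#' @inheritParams cmdl_cost
#' @return The cost (scalar).
#' @export
rmdl_cost <- function(decomp, k) {
  .mdl_cost_at(decomp, k, "rmdl")
}

.mdl_cost_at <- function(decomp, k, criterion) {
  coefs <- as_coefficients(decomp)
  n <- length(coefs)
  k <- as.integer(k)
  if (k < 1L || k > mdl_kmax(n)) {
    stop(sprintf("k must be in [1, %d] for n = %d", mdl_kmax(n), n), call. = FALSE)
  }
  s2 <- sort(coefs^2, decreasing = TRUE)
  unname(.mdl_cost_curve(s2, criterion)[k])
}

#' Full MDL cost curve over the admissible model orders
#'
#' @inheritParams cmdl_cost
#' @param criterion `"rmdl"` or `"cmdl"`.
#' @return Named numeric vector of costs for `k = 1, ..., mdl_kmax(n)`.
#' @export
mdl_cost_curve <- function(decomp, criterion = c("rmdl", "cmdl")) {
  criterion <- match.arg(criterion)
  coefs <- as_coefficients(decomp)
  .mdl_cost_curve(sort(coefs^2, decreasing = TRUE), criterion)
}

#' Select the MDL-optimal number of retained coefficients
#'
#' Minimises the chosen MDL cost over `k = 1, ..., mdl_kmax(n)`. The retained
#' set gamma always consists of the `k` largest coefficients by absolute
#' value, with ties broken stably (larger magnitude first, then lower index).
#' Cost ties resolve to the smallest `k` (the simpler model). An all-zero
#' coefficient vector has no defined selection and returns the `k = 0`
#' sentinel with a warning.
#'
#' @inheritParams mdl_cost_curve
#' @return Object of class `mdl_selection`: fields `criterion`, `k`, `gamma`
#'   (indices of retained coefficients), `S_total`, `S_gamma`, `cost_curve`,
#'   `n`, `degenerate` (TRUE where the curve hit a `-Inf` sentinel).
#' @export
#' @examples
#' d <- dwt_forward(rnorm(64), wavelet_spec())
#' sel <- select_k(d, "rmdl")
#' sel$k <= mdl_kmax(d$n)
select_k <- function(decomp, criterion = c("rmdl", "cmdl")) {
  criterion <- match.arg(criterion)
  coefs <- as_coefficients(decomp)
  n <- length(coefs)
  if (n < 4L) stop("need at least 4 coefficients to select k", call. = FALSE)
  if (all(coefs == 0)) {
    warning("all coefficients are zero; MDL selection undefined (k = 0 sentinel)")
    return(structure(list(criterion = criterion, k = 0L, gamma = integer(0),
                          S_total = 0, S_gamma = 0,
                          cost_curve = numeric(0), n = n, degenerate = TRUE),
                     class = "mdl_selection"))
  }
  ord <- order(-abs(coefs), seq_along(coefs)) # stable tie-break
  s2 <- coefs[ord]^2
  curve <- .mdl_cost_curve(s2, criterion)
  k <- which.min(curve) # first minimum = smallest k on ties
  structure(list(criterion = criterion,
                 k = as.integer(k),
                 gamma = sort(ord[seq_len(k)]),
                 S_total = sum(s2),
                 S_gamma = sum(s2[seq_len(k)]),
                 cost_curve = curve,
                 n = n,
                 degenerate = any(is.infinite(curve))),
            class = "mdl_selection")
}

#' @export
print.mdl_selection <- function(x, ...) {
  cat(sprintf("MDL selection (%s): k = %d of n = %d (retained energy %.4g of %.4g)\n",
              x$criterion, x$k, x$n, x$S_gamma, x$S_total))
  invisible(x)
}

#' Denoise one time series by MDL wavelet thresholding
#'
#' Transforms the series with the orthonormal DWT, keeps the MDL-selected
#' `k` largest-magnitude detail coefficients (zeroing the rest), and inverts.
#' The coarsest-level approximation coefficients are always retained outside
#' the competition: they encode the series baseline/mean, which the MDL costs
#' do not contemplate deleting. If the detail coefficients are all zero the
#' selection is undefined and the input is returned unchanged with a warning.
#'
#' @param series numeric vector (finite-valued).
#' @param spec a [wavelet_spec()].
#' @param criterion `"rmdl"` (default) or `"cmdl"`.
#' @return The denoised series (same length as the input), with attribute
#'   `"k"` giving the selected detail model order.
#' @export
denoise_series <- function(series, spec = wavelet_spec(),
                           criterion = c("rmdl", "cmdl")) {
  criterion <- match.arg(criterion)
  d <- dwt_forward(series, spec)
  na <- d$approx_length
  detail_idx <- seq.int(na + 1L, d$n)
  details <- d$coefficients[detail_idx]
  # "zero" up to roundoff of the transform (constant series leave ~1e-16)
  if (max(abs(details)) <= 1e-12 * max(abs(d$coefficients))) {
    warning("all detail coefficients are zero; returning the input unchanged")
    out <- series
    attr(out, "k") <- 0L
    return(out)
  }
  sel <- select_k(details, criterion)
  keep <- rep(FALSE, length(details))
  keep[sel$gamma] <- TRUE
  coefs <- d$coefficients
  coefs[detail_idx[!keep]] <- 0
  out <- dwt_inverse(d, coefs)
  attr(out, "k") <- sel$k
  out
}

#' Denoise every voxel of every run of a dataset
#'
#' Applies [denoise_series()] per voxel and per run (runs are denoised
#' independently, before any concatenation), using a single matrix-valued
#' transform per run for speed.
#'
#' @param dataset a `bold_dataset`.
#' @inheritParams denoise_series
#' @return The denoised `bold_dataset`, with a data frame attribute
#'   `"mdl_k"` (columns `voxel_id`, `run`, `k`) reporting the selected model
#'   order per voxel and run.
#' @export
denoise_dataset <- function(dataset, spec = wavelet_spec(),
                            criterion = c("rmdl", "cmdl")) {
  stopifnot(inherits(dataset, "bold_dataset"))
  criterion <- match.arg(criterion)
  krep <- list()
  runs <- lapply(seq_along(dataset$runs), function(r) {
    Y <- dataset$runs[[r]]
    fwd <- .dwt_forward_matrix(Y, spec)
    na <- fwd$approx_length
    C <- fwd$coefficients
    detail_idx <- seq.int(na + 1L, fwd$n)
    ks <- integer(nrow(Y))
    for (v in seq_len(nrow(Y))) {
      details <- C[v, detail_idx]
      if (max(abs(details)) <= 1e-12 * max(abs(C[v, ]))) next # nothing to threshold
      ord <- order(-abs(details), seq_along(details))
      k <- which.min(.mdl_cost_curve(details[ord]^2, criterion))
      C[v, detail_idx[ord[-seq_len(k)]]] <- 0
      ks[v] <- k
    }
    krep[[r]] <<- data.frame(voxel_id = dataset$voxel_ids, run = r, k = ks,
                             stringsAsFactors = FALSE)
    .dwt_inverse_matrix(C, fwd)
  })
  out <- new_bold_dataset(runs, dataset$tr_seconds, dataset$voxel_ids,
                          dataset$group_label, dataset$schedule,
                          discarded = dataset$discarded)
  attr(out, "mdl_k") <- do.call(rbind, krep)
  out
}
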