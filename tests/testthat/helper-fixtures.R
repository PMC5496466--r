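# Small shared fixtures, built in code.

# A compact configuration for fast simulation-heavy tests: 2 runs of 64
# volumes, 7 trials per run, small ROI. Keeps the default timing (TR, window,
# pair spacing) so scan arithmetic stays the same as the full design.
small_config <- function(...) {
  experiment_config(volumes_per_run = 64L, n_runs = 2L, trials_per_run = 7L,
                    n_active_voxels = 12L, n_inactive_voxels = 12L, ...)
}

# Noiseless configuration (both groups at infinite SNR).
noiseless_config <- function(...) {
  small_config(group_snr = c(young = Inf, nondemented = Inf), ...)
}

# Independent brute-force oracle for MDL model-order selection: evaluates the
# published cost term by term for every admissible k, recomputing energies
# from a fresh sort each time. Deliberately naive.
oracle_select_k <- function(coefs, criterion) {
  n <- length(coefs)
  kmax <- floor(0.95 * n)
  if (kmax >= 0.95 * n) kmax <- kmax - 1 # strict bound
  kmax <- min(kmax, n - 1)
  mags <- sort(abs(coefs), decreasing = TRUE)
  S <- sum(coefs^2)
  best_k <- NA_integer_
  best_cost <- Inf
  for (k in seq_len(kmax)) {
    Sg <- sum(mags[1:k]^2)
    resid <- S - Sg
    cost <- if (resid <= 0 || Sg <= 0) {
      -Inf
    } else if (criterion == "cmdl") {
      ((n - k) / 2) * log(resid / (n - k)) + (k / 2) * log(Sg / k) +
        0.5 * log(k * (n - k))
    } else {
      ((n - k) / 2) * log(resid / (n - k)^3) + (k / 2) * log(Sg / k^3)
    }
    if (cost < best_cost) { # strict: first (smallest) k wins ties
      best_cost <- cost
      best_k <- k
    }
  }
  best_k
}
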