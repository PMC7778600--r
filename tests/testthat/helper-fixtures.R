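# small in-code fixtures shared across test files

# smooth peak-on-baseline spectrum, deterministic
smooth_spectrum <- function(n = 200, x0 = 500, step = 2) {
  x <- seq(x0, by = step, length.out = n)
  y <- 50 + 0.01 * (x - x0) + 80 * exp(-(x - (x0 + n))^2 / (2 * 40^2))
  raman_spectrum(x, y)
}

# replicate collection: template + iid gaussian noise
noisy_replicates <- function(template, n_rep, sd, seed) {
  praman:::with_seed(seed, {
    spectra <- lapply(seq_len(n_rep), function(i)
      raman_spectrum(template$axis,
                     template$intensity + rnorm(length(template$axis), 0, sd)))
    spectrum_collection(spectra)
  })
}

collection_scale <- function(coll, k) {
  spectrum_collection(lapply(coll$spectra, function(s)
    raman_spectrum(s$axis, k * s$intensity)), labels = coll$labels)
}

# dense, independent re-implementation of the asymmetric penalised
# least-squares baseline (the oracle for the sparse solver)
dense_asls_oracle <- function(y, lam, p, iters) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lam * t(D) %*% D
  w <- rep(1, n)
  z <- y
  for (k in seq_len(iters)) {
    A <- diag(w) + P
    z <- solve(A, w * y)
    # same structured refinement step as the implementation under test,
    # via base solve() on the dense system
    r <- w * (y - z) - lam * as.numeric(t(D) %*% (D %*% z))
    z <- z + solve(A, r)
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  z
}

# brute-force despike flag oracle: explicit per-channel scan
despike_flag_oracle <- function(y, spike_z) {
  d <- diff(y)
  med <- median(d)
  mad <- median(abs(d - med))
  if (mad == 0) return(rep(FALSE, length(y)))
  z <- 0.6745 * abs(d - med) / mad
  n <- length(y)
  flags <- logical(n)
  for (i in seq_len(n)) {
    touching <- z[intersect(c(i - 1, i), seq_len(n - 1))]
    flags[i] <- all(touching > spike_z)
  }
  flags
}
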