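# Independent brute-force oracle for the gapped-dipeptide sums: a literal
# triple loop over (i, j, k), no shared code with the package implementation.
naive_gapdpc <- function(P, g) {
  L <- nrow(P)
  out <- numeric(400)
  for (i in 1:20) {
    for (j in 1:20) {
      s <- 0
      for (k in seq_len(L - g - 1)) s <- s + P[k, i] * P[k + g + 1, j]
      out[(i - 1) * 20 + j] <- s
    }
  }
  out
}

# Scaled profile with a constant matrix value.
constant_profile <- function(L, value) {
  pssm_profile(matrix(value, L, 20), strrep("A", L), scaled = TRUE)
}

# Scaled profile from an explicit matrix (sequence is arbitrary).
profile_from_matrix <- function(m, scaled = TRUE) {
  pssm_profile(m, strrep("A", nrow(m)), scaled = scaled)
}

# Near-indicator row: ~1 at column `hot`, ~0 elsewhere, strictly in (0, 1).
indicator_row <- function(hot, eps = 1e-8) {
  r <- rep(eps, 20)
  r[hot] <- 1 - eps
  r
}

# Tiny linearly separable two-class feature dataset.
separable_dataset <- function(n_per_class = 15, d = 5, gap = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * d), ncol = d)
  x[1:n_per_class, 1] <- x[1:n_per_class, 1] + gap
  pssm_dataset(x, rep(c("pos", "neg"), each = n_per_class))
}
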