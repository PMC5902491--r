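# Fixtures are built in code; nothing is read from disk.

# Wrap a 3D array of H values as a hurst_map (all voxels defined unless NA).
make_map <- function(values) {
  values <- as.array(values)
  structure(list(values = values,
                 mask = !is.na(values),
                 undefined = array(FALSE, dim(values)),
                 r_squared = array(NA_real_, dim(values)),
                 scales = integer(0), corrected = FALSE),
            class = "hurst_map")
}

# Gaussian feature matrix with a known mean shift on `affected` columns of
# the MCI group; bypasses the imaging pipeline for fast classifier tests.
make_toy_fm <- function(n_mci = 15, n_hc = 15, k = 20, affected = integer(0),
                        shift = 0, sd = 1, seed = 1) {
  boldhurst:::with_seed(seed, {
    vals <- matrix(rnorm((n_mci + n_hc) * k, sd = sd), n_mci + n_hc, k)
    if (length(affected)) {
      vals[seq_len(n_mci), affected] <- vals[seq_len(n_mci), affected] + shift
    }
    feature_matrix(vals, c(rep("MCI", n_mci), rep("HC", n_hc)))
  })
}

# O(n^2) pairwise-concordance AUC (ties count one half): the independent
# oracle for the rank-based implementation.
auc_brute <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
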