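# shared fixtures and independent oracles

# one-row composition without file I/O
comp1 <- function(diet_id = "X", cp = 0, ahf = 0, tdf = 0, ash = 0,
                  ge = NA_real_) {
  proximate_composition(diet_id, cp = cp, ahf = ahf, tdf = tdf, ash = ash,
                        ge = ge)
}

# random valid composition rows (macro sum kept under 100)
random_comp <- function(n, seed) {
  set.seed(seed)
  parts <- matrix(stats::runif(4 * n), ncol = 4)
  parts <- parts / rowSums(parts) * stats::runif(n, 20, 95)
  df <- data.frame(diet_id = sprintf("D%03d", seq_len(n)),
                   dm_pct = 92, ash = parts[, 1], cp = parts[, 2],
                   ahf = parts[, 3], tdf = parts[, 4],
                   tif = parts[, 4], tsf = 0, ge = 5.5)
  composition_table(df)
}

# significance matrix implied by a compact letter display: two groups
# differ iff they share no letter
matrix_from_letters <- function(cld) {
  gs <- names(cld)
  sets <- strsplit(cld, "")
  m <- matrix(FALSE, length(gs), length(gs), dimnames = list(gs, gs))
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (i != j) m[i, j] <- length(intersect(sets[[i]], sets[[j]])) == 0L
    }
  }
  m
}

# all symmetric significance patterns over k groups, as logical matrices
all_sig_patterns <- function(k, group_names = LETTERS[seq_len(k)]) {
  npairs <- k * (k - 1L) / 2L
  idx <- which(upper.tri(matrix(0, k, k)))
  lapply(seq_len(2^npairs) - 1L, function(code) {
    bits <- as.logical(bitwAnd(code, 2^(seq_len(npairs) - 1L)))
    m <- matrix(FALSE, k, k, dimnames = list(group_names, group_names))
    m[idx] <- bits
    m | t(m)
  })
}

zero_noise_sd <- function() c(DM = 0, OM = 0, AHF = 0, GE = 0, N = 0, AA = 0)
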