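# Programmatic fixtures shared across the suite. Everything is generated in
# code so the repository carries no data files.

# A small synthetic study (6 compounds by default) on the 2 x 3 design.
tiny_study <- function(n = 6, sigma = 0, seed = 11, p = 12) {
  generate_study(synthetic_spec(
    n_compounds = n, p_descriptors = p, n_informative = 2,
    n_blocks = 1, block_size = 3, sigma = sigma, seed = seed))
}

# Write a study to CSVs in a temp dir; returns the three paths.
study_csvs <- function(study, dir = tempfile("study")) {
  write_study(study, dir)
}

# Brute-force census of fully separable subsets (independent of the clique
# path): enumerate every subset of each size with utils::combn and test the
# all-pairs resolution rule directly.
bf_count_separable <- function(rt, sizes, config) {
  n <- length(rt)
  sapply(sizes, function(k) {
    cmb <- combn(n, k)
    sum(apply(cmb, 2, function(ix) {
      pr <- combn(ix, 2)
      rs <- abs(rt[pr[1, ]] - rt[pr[2, ]]) / config$peak_width
      all(rs >= config$rs_limit)
    }))
  })
}

# Brute-force agreement curve (both-separated counts) by direct enumeration.
bf_both_separated <- function(rt_exp, rt_model, sizes, config) {
  n <- length(rt_exp)
  sep <- function(rt, ix) {
    pr <- combn(ix, 2)
    all(abs(rt[pr[1, ]] - rt[pr[2, ]]) / config$peak_width >= config$rs_limit)
  }
  sapply(sizes, function(k) {
    cmb <- combn(n, k)
    sum(apply(cmb, 2, function(ix) sep(rt_exp, ix) && sep(rt_model, ix)))
  })
}

# Brute-force clique counts of an arbitrary adjacency matrix (n <= 12):
# enumerate every subset of each size and check all pairs directly.
bf_clique_counts <- function(adj, sizes) {
  n <- nrow(adj)
  sapply(sizes, function(k) {
    if (k > n) return(0)
    cmb <- combn(n, k)
    sum(apply(cmb, 2, function(ix) {
      pr <- combn(ix, 2)
      all(adj[cbind(pr[1, ], pr[2, ])])
    }))
  })
}

# Pack a logical adjacency matrix into the per-vertex bitmask form the
# enumeration core consumes.
adj_to_masks <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    sum(bitwShiftL(1L, which(adj[i, ]) - 1L))
  }, integer(1))
}

# A random "separation" retention vector whose pair graph has mixed edges.
random_rt <- function(n, seed, spread = 1.5) {
  set.seed(seed)
  rt <- cumsum(runif(n, 0, spread)) + 1
  names(rt) <- sprintf("c%02d", seq_len(n))
  rt
}
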