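# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: descendant tips are found by naive recursion,
# ANOSIM R by explicit double loops, and permutations by brute enumeration.

# tips (labels) descending from `node`, by recursion over the edge table
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

# brute-force branch-by-branch weighted UniFrac for two proportion vectors
# named by tip label
brute_unifrac <- function(tree, p, q, normalized = TRUE) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(tree$edge))) {
    tips <- descendant_tips(tree, tree$edge[i, 2])
    pa <- sum(p[tips])
    pb <- sum(q[tips])
    num <- num + tree$edge.length[i] * abs(pa - pb)
    den <- den + tree$edge.length[i] * (pa + pb)
  }
  if (normalized) num / den else num
}

# ANOSIM R from first principles: explicit loops over sample pairs
brute_anosim_R <- function(dmat, groups) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  dv <- c()
  within <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dv <- c(dv, dmat[i, j])
      within <- c(within, groups[i] == groups[j])
    }
  }
  rk <- rank(dv)
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

# all permutations of a vector, recursively
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# two-isomer toy species table for quotient/equilibrium tests: A and B are
# fictitious neutral isomers (same formula), so A -> B balances trivially
toy_isomer_species <- function(dgf_a = -100, dgf_b = -110) {
  sp <- species_data()
  sp <- add_species(sp, "isoA", "C2H4O2", 0, dgf_a)
  add_species(sp, "isoB", "C2H4O2", 0, dgf_b)
}
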