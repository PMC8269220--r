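make_abund <- function(counts, lengths = NULL, libs = NULL) {
  if (is.null(lengths)) lengths <- setNames(rep(2e6, nrow(counts)), rownames(counts))
  if (is.null(libs)) libs <- setNames(pmax(colSums(counts) * 2, 1e6), colnames(counts))
  abundance_matrix(counts, lengths, libs)
}

test_that("RPKM is counts per kb per million mapped reads", {
  counts <- matrix(c(1000, 0), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  am <- abundance_matrix(counts, c(g1 = 2e6, g2 = 1e6), c(s1 = 1e6))
  r <- rpkm(am)
  expect_equal(r["g1", "s1"], 0.5)  # 1000 / (2000 kb * 1 M reads)
  expect_equal(r["g2", "s1"], 0)
  # brute-force elementwise oracle on a random 5 x 4 table
  set.seed(41)
  counts <- matrix(rpois(20, 500), 5, 4,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  lengths <- setNames(runif(5, 1.5e6, 3e6), rownames(counts))
  libs <- setNames(round(runif(4, 1e5, 1e6)), colnames(counts))
  am <- abundance_matrix(counts, lengths, libs)
  r <- rpkm(am)
  for (g in rownames(counts)) {
    for (s in colnames(counts)) {
      expect_equal(r[g, s],
                   counts[g, s] / ((lengths[[g]] / 1e3) * (libs[[s]] / 1e6)))
    }
  }
})

test_that("abundance matrix validation enforces its invariants", {
  counts <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(abundance_matrix(counts, c(g1 = 2e6), c(s1 = 1e6, s2 = 1e6)),
               "genome_lengths")
  expect_error(abundance_matrix(counts, c(g1 = 2e6, g2 = 2e6), c(s1 = 2, s2 = 2)),
               "library sizes")
  expect_error(rpkm(abundance_matrix(counts * 0, c(g1 = 2e6, g2 = 2e6),
                                     c(s1 = 0, s2 = 1e6))),
               "zero library size")
})

test_that("TPM columns are rescaled to exactly one million", {
  set.seed(42)
  counts <- matrix(rpois(12, 300), 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  counts[, 4] <- 0
  am <- make_abund(counts, lengths = setNames(c(1.5e6, 2e6, 3e6), rownames(counts)))
  tt <- tpm(am)
  expect_equal(unname(colSums(tt)[1:3]), rep(1e6, 3))
  expect_equal(unname(tt[, 4]), rep(0, 3))
  # single-genome sample
  am1 <- make_abund(matrix(50, 1, 1, dimnames = list("g1", "s1")))
  expect_equal(tpm(am1)[1, 1], 1e6)
  # 3-genome hand computation
  rate <- counts[, 1] / (c(1.5e6, 2e6, 3e6) / 1e3)
  expect_equal(unname(tt[, 1]), unname(1e6 * rate / sum(rate)))
})

test_that("RPKM and TPM ignore duplicated samples; log transform is monotone", {
  set.seed(43)
  counts <- matrix(rpois(9, 200), 3, 3,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  am <- make_abund(counts)
  dup <- cbind(counts, s4 = counts[, "s1"])
  am_dup <- abundance_matrix(dup, am$genome_lengths,
                             c(am$library_sizes, s4 = am$library_sizes[["s1"]]))
  expect_equal(rpkm(am_dup)[, 1:3], rpkm(am))
  expect_equal(tpm(am_dup)[, 1:3], tpm(am))

  r <- rpkm(am)
  expect_equal(log_transform(matrix(1), pseudocount = 0)[1], 0)
  lt <- log_transform(r)
  expect_true(all(is.finite(lt)))
  expect_equal(order(lt[, 1]), order(r[, 1]))
})

test_that("weighted UniFrac matches hand and brute-force branch sums", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  ab <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("A", "B"), c("x", "y")))
  d <- weighted_unifrac(two, ab)
  expect_equal(d["x", "y"], 1)            # disjoint communities, max distance
  expect_equal(d["x", "x"], 0)
  same <- matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2,
                 dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(weighted_unifrac(two, same)["x", "y"], 0)

  # 4-tip tree against the naive branch-by-branch oracle
  four <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,D:1):0.75);")
  ab4 <- matrix(c(5, 5, 0, 0, 0, 4, 1, 5), 4, 2,
                dimnames = list(c("A", "B", "C", "D"), c("x", "y")))
  p <- ab4[, 1] / sum(ab4[, 1]); q <- ab4[, 2] / sum(ab4[, 2])
  expect_equal(weighted_unifrac(four, ab4)["x", "y"],
               brute_unifrac(four, p, q, normalized = TRUE))
  expect_equal(weighted_unifrac(four, ab4, normalized = FALSE)["x", "y"],
               brute_unifrac(four, p, q, normalized = FALSE))
  # genomes missing from the tree are reported by name
  bad <- rbind(ab4, E = c(1, 1))
  expect_error(weighted_unifrac(four, bad), "E")
})

test_that("weighted UniFrac agrees with an independent reference implementation", {
  skip_if_not_installed("phyloseq")
  sc <- simulate_counts(n_genomes = 8, n_samples = 6, seed = 9)
  tree <- simulate_tree(8, seed = 9)
  mat <- tpm(sc$abundance)
  ours <- weighted_unifrac(tree, mat, normalized = TRUE)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(mat, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tree))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-10)
})

test_that("raw weighted UniFrac satisfies the triangle inequality on random trees", {
  for (seed in 1:10) {
    sc <- simulate_counts(n_genomes = 6, n_samples = 5, seed = seed)
    tree <- simulate_tree(6, seed = seed)
    d <- weighted_unifrac(tree, rpkm(sc$abundance), normalized = FALSE)
    n <- nrow(d)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("PCoA round-trips Euclidean configurations and orders axes", {
  # points on a line: first axis recovers spacing up to sign/translation
  x <- c(0, 1, 3, 6)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  p <- pcoa(d, n_axes = 1)
  rec <- p$coordinates[, 1]
  expect_equal(as.matrix(dist(rec)), d, ignore_attr = TRUE, tolerance = 1e-10)
  # 2-D configuration reproduced to 1e-8
  set.seed(5)
  pts <- matrix(rnorm(16), 8, 2)
  d2 <- as.matrix(dist(pts))
  p2 <- pcoa(d2, n_axes = 2)
  expect_equal(as.matrix(dist(p2$coordinates)), d2, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p2$eigenvalues) <= 1e-9))
  # equidistant triple: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  p3 <- suppressWarnings(pcoa(d3, n_axes = 3))
  eig <- p3$eigenvalues[p3$eigenvalues > 1e-9]
  expect_length(eig, 2)
  expect_equal(eig[1], eig[2])
})

test_that("ANOSIM matches exhaustive enumeration and an external reference", {
  # 6-sample instance with clear but imperfect separation
  set.seed(17)
  pts <- c(rnorm(3, 0), rnorm(3, 1.5))
  d <- as.matrix(dist(pts))
  g <- rep(c("u", "v"), each = 3)
  res <- anosim(d, g, n_permutations = 999, seed = 3)
  expect_equal(res$statistic, brute_anosim_R(d, g))
  ex <- anosim(d, g, exact = TRUE)
  expect_equal(ex$statistic, res$statistic)
  # exact p from full enumeration with the independent R oracle
  perms <- all_perms(1:6)
  r_all <- vapply(perms, function(p) brute_anosim_R(d, g[p]), 0)
  expect_equal(ex$p_value, mean(r_all >= ex$statistic - 1e-12))
  # Monte-Carlo p within binomial error of the exact p (999 permutations)
  expect_lt(abs(res$p_value - ex$p_value), 0.04)

  skip_if_not_installed("vegan")
  sc <- simulate_counts(seed = 21, effect_size = 0.5)
  dd <- weighted_unifrac(simulate_tree(20, seed = 21), tpm(sc$abundance))
  ours <- anosim(dd, sc$grouping, n_permutations = 499, seed = 1)
  ref <- vegan::anosim(as.dist(dd), sc$grouping, permutations = 499)
  expect_equal(ours$statistic, unname(ref$statistic))
})

test_that("ANOSIM boundary cases: perfect separation and degenerate designs", {
  d <- matrix(0, 6, 6)
  within_pairs <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  for (k in seq_len(nrow(within_pairs))) {
    d[within_pairs[k, 1], within_pairs[k, 2]] <- runif(1, 0, 1)
  }
  d[upper.tri(d) & d == 0] <- runif(sum(upper.tri(d) & d == 0), 2, 3)
  d <- d + t(d)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(anosim(d, g, n_permutations = 99, seed = 1)$statistic, 1)
  expect_error(anosim(d, rep("a", 6), 99), ">= 2 groups")
  expect_error(anosim(d, c("a", rep("b", 5)), 99), ">= 2 samples")
})

test_that("abundance regressions recover exact fits and hand OLS", {
  x <- c(2, 4, 6, 8, 10)
  f <- abundance_regression(-2 * x + 1, x)
  expect_equal(f$slope, -2)
  expect_equal(f$intercept, 1)
  expect_lt(f$p_value, 1e-12)
  # 5-point hand computation: slope = Sxy/Sxx, intercept = ybar - b xbar
  y <- c(3.1, 2.8, 4.0, 4.9, 5.2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  f2 <- abundance_regression(y, x)
  expect_equal(f2$slope, b)
  expect_equal(f2$intercept, a)
  expect_error(abundance_regression(y, rep(1, 5)), "variance")
  expect_error(abundance_regression(y[1:2], x[1:2]), "3 paired")
})

test_that("regression p-values are calibrated under the null", {
  set.seed(99)
  x <- rnorm(20)
  p <- replicate(400, abundance_regression(rnorm(20), x)$p_value)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.03)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("per-genome regression tables support BH adjustment", {
  sc <- simulate_counts(seed = 4)
  temp <- rnorm(12, 20, 5)
  tab <- abundance_regressions(rpkm(sc$abundance), temp, p_adjust = "BH")
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12))
})
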