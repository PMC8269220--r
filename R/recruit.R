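#' Genome-by-sample read-recruitment abundance matrix
#'
#' @param counts numeric matrix of filtered mapped-read counts, genomes in
#'   rows and samples in columns, with dimnames.
#' @param genome_lengths named vector, bp per genome (all row names covered).
#' @param library_sizes named vector, total reads per sample; must be at
#'   least the per-sample count sums.
#' @param sample_metadata optional data frame keyed by sample name
#'   (latitude, depth, temperature, salinity, region, ...).
#' @return object of class `ecophys_abund`.
#' @export
abundance_matrix <- function(counts, genome_lengths, library_sizes,
                             sample_metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have genome row names and sample column names")
  }
  if (any(counts < 0)) stop("counts must be >= 0")
  if (!all(rownames(counts) %in% names(genome_lengths))) {
    stop("genome_lengths missing entries for some genomes")
  }
  if (!all(colnames(counts) %in% names(library_sizes))) {
    stop("library_sizes missing entries for some samples")
  }
  gl <- genome_lengths[rownames(counts)]
  ls <- library_sizes[colnames(counts)]
  if (any(gl <= 0)) stop("genome lengths must be > 0")
  if (any(ls < colSums(counts))) {
    stop("library sizes must be >= per-sample count sums")
  }
  if (!is.null(sample_metadata)) {
    if (!all(colnames(counts) %in% rownames(sample_metadata))) {
      stop("sample_metadata missing rows for some samples")
    }
    sample_metadata <- sample_metadata[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, genome_lengths = gl, library_sizes = ls,
                 sample_metadata = sample_metadata),
            class = "ecophys_abund")
}

#' Read an abundance matrix from TSV files
#'
#' @param counts_file genome x sample TSV (first column = genome names).
#' @param lengths_file two-column TSV `genome`, `length_bp`.
#' @param libsizes_file two-column TSV `sample`, `library_size`.
#' @param metadata_file optional TSV keyed by a `sample` column.
#' @return an `ecophys_abund`.
#' @export
read_abundance_matrix <- function(counts_file, lengths_file, libsizes_file,
                                  metadata_file = NULL) {
  counts <- as.matrix(utils::read.delim(counts_file, row.names = 1,
                                        check.names = FALSE))
  len <- utils::read.delim(lengths_file)
  lib <- utils::read.delim(libsizes_file)
  meta <- NULL
  if (!is.null(metadata_file)) {
    meta <- utils::read.delim(metadata_file, stringsAsFactors = FALSE)
    rownames(meta) <- meta$sample
  }
  abundance_matrix(counts,
                   stats::setNames(len[[2]], len[[1]]),
                   stats::setNames(lib[[2]], lib[[1]]),
                   meta)
}

#' Reads per kilobase per million (RPKM)
#'
#' RPKM[g, s] = counts[g, s] / (genome length in kb x library size in
#' millions): a length- and depth-normalized recruitment abundance.
#'
#' @param x an `ecophys_abund`.
#' @return genome x sample matrix of RPKM values.
#' @export
rpkm <- function(x) {
  stopifnot(inherits(x, "ecophys_abund"))
  if (any(x$library_sizes == 0)) stop("zero library size")
  len_kb <- x$genome_lengths / 1e3
  lib_m <- x$library_sizes / 1e6
  sweep(sweep(x$counts, 1, len_kb, "/"), 2, lib_m, "/")
}

#' Transcripts-per-million-style normalization (TPM)
#'
#' Per sample, length-normalized rates counts/length_kb are rescaled to sum
#' to 1e6, so every nonzero column sums to exactly one million; all-zero columns
#' stay all-zero.
#'
#' @param x an `ecophys_abund`.
#' @return genome x sample matrix of TPM values.
#' @export
tpm <- function(x) {
  stopifnot(inherits(x, "ecophys_abund"))
  rate <- sweep(x$counts, 1, x$genome_lengths / 1e3, "/")
  cs <- colSums(rate)
  out <- sweep(rate, 2, ifelse(cs > 0, cs, 1), "/") * 1e6
  out[, cs == 0] <- 0
  out
}

#' Log10 transform with pseudocount
#'
#' @param x nonnegative matrix (e.g. RPKM values).
#' @param pseudocount added before taking log10; the default is half the
#'   smallest nonzero entry, so zeros map to a finite value just below the
#'   observed dynamic range.
#' @return log10(x + pseudocount), same shape as `x`.
#' @export
log_transform <- function(x, pseudocount = NULL) {
  if (any(x < 0)) stop("entries must be >= 0")
  if (is.null(pseudocount)) {
    nz <- x[x > 0]
    if (!length(nz)) stop("all entries are zero; supply a pseudocount")
    pseudocount <- min(nz) / 2
  }
  log10(x + pseudocount)
}

## edge x sample matrix of descendant-tip abundance proportions.
.branch_proportions <- function(tree, abund) {
  tips <- tree$tip.label
  missing <- setdiff(rownames(abund)[rowSums(abund) > 0], tips)
  if (length(missing)) {
    stop("abundances given for genomes absent from the tree: ",
         paste(missing, collapse = ", "))
  }
  ntip <- length(tips)
  p <- matrix(0, ntip, ncol(abund), dimnames = list(tips, colnames(abund)))
  present <- intersect(rownames(abund), tips)
  p[present, ] <- abund[present, , drop = FALSE]
  cs <- colSums(p)
  if (any(cs == 0)) stop("samples with zero total abundance: ",
                         paste(colnames(abund)[cs == 0], collapse = ", "))
  p <- sweep(p, 2, cs, "/")
  nnode <- tree$Nnode
  node_p <- rbind(p, matrix(0, nnode, ncol(abund)))
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (i in seq_len(nrow(edge))) {
    node_p[edge[i, 1], ] <- node_p[edge[i, 1], ] + node_p[edge[i, 2], ]
  }
  node_p[tree$edge[, 2], , drop = FALSE]   # one row per edge, in edge order
}

#' Weighted UniFrac distances between samples
#'
#' For samples A and B with tip relative abundances p and q, the raw
#' weighted UniFrac distance is sum over branches of
#' l_b * |P_A(b) - P_B(b)| where P(b) is the total proportion of tips
#' descending from branch b; the normalized variant (the default) divides by
#' sum of l_b * (P_A(b) + P_B(b)) and lies in [0, 1]. Unrooted trees are
#' midpoint-rooted first.
#'
#' @param tree an `ape::phylo` with branch lengths; tips are genome names.
#' @param abund genome x sample abundance matrix (any nonnegative units;
#'   converted to proportions per sample).
#' @param normalized divide by the maximal attainable branch sum (default
#'   `TRUE`).
#' @return square symmetric distance matrix with zero diagonal.
#' @export
weighted_unifrac <- function(tree, abund, normalized = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  ep <- .branch_proportions(tree, as.matrix(abund))
  l <- tree$edge.length
  ns <- ncol(ep)
  d <- matrix(0, ns, ns, dimnames = list(colnames(ep), colnames(ep)))
  for (i in seq_len(ns - 1)) {
    for (j in seq((i + 1), ns)) {
      num <- sum(l * abs(ep[, i] - ep[, j]))
      if (normalized) {
        den <- sum(l * (ep[, i] + ep[, j]))
        d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
      } else {
        d[i, j] <- d[j, i] <- num
      }
    }
  }
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers -D^2/2 and eigendecomposes it (via [stats::cmdscale()]),
#' returning sample coordinates on the leading axes ordered by eigenvalue.
#' Axes with negative eigenvalues are reported but never returned as
#' coordinates.
#'
#' @param distances square symmetric dissimilarity matrix (or `dist`).
#' @param n_axes number of axes requested (default 3); truncated with a
#'   warning when fewer positive eigenvalues exist.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   sorted decreasing) and `proportion_explained` (over positive
#'   eigenvalues).
#' @export
pcoa <- function(distances, n_axes = 3) {
  d <- stats::as.dist(distances)
  n <- attr(d, "Size")
  ## k = n - 1 requests every axis; cmdscale warns when some have
  ## non-positive eigenvalues, which we report explicitly below instead.
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_axes > npos) {
    warning("only ", npos, " positive eigenvalues; returning ", npos, " axes")
    n_axes <- npos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = pmax(eig, 0) / sum(pmax(eig, 0)))
}

## Rank-based ANOSIM R for a lower-triangle distance vector and a grouping.
.anosim_R <- function(ranks, same_group, n) {
  (mean(ranks[!same_group]) - mean(ranks[same_group])) / (n * (n - 1) / 4)
}

.all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .all_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test comparing between-group and within-group
#' community distances:
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4),
#' with R in [-1, 1]; R near 0 means groups are indistinguishable, R near 1
#' means all between-group distances exceed all within-group ones. The
#' p-value is (1 + number of permuted R >= observed R) / (1 + permutations),
#' or the exact proportion over all label permutations when `exact = TRUE`
#' (only feasible for small n).
#'
#' @param distances square symmetric dissimilarity matrix (or `dist`).
#' @param grouping vector of group labels, one per sample; at least two
#'   groups with at least two samples each.
#' @param n_permutations Monte-Carlo permutations (default 999).
#' @param seed optional integer seed recorded in the output.
#' @param exact enumerate all label permutations instead (n <= 9).
#' @return list with `statistic` (R), `p_value`, `n_permutations`, `seed`
#'   and `method`.
#' @export
anosim <- function(distances, grouping, n_permutations = 999, seed = NULL,
                   exact = FALSE) {
  d <- as.matrix(stats::as.dist(distances))
  n <- nrow(d)
  grouping <- as.factor(grouping)
  if (length(grouping) != n) stop("grouping length must match sample count")
  if (nlevels(droplevels(grouping)) < 2 || any(table(grouping) < 2)) {
    stop("ANOSIM needs >= 2 groups with >= 2 samples each")
  }
  lt <- lower.tri(d)
  ranks <- rank(d[lt])
  pair_i <- row(d)[lt]
  pair_j <- col(d)[lt]
  same <- function(g) g[pair_i] == g[pair_j]
  r_obs <- .anosim_R(ranks, same(grouping), n)
  if (exact) {
    if (n > 9) stop("exact enumeration limited to 9 samples")
    perms <- .all_permutations(seq_len(n))
    r_all <- vapply(perms, function(p) .anosim_R(ranks, same(grouping[p]), n), 0)
    p_val <- mean(r_all >= r_obs - 1e-12)
    return(list(statistic = r_obs, p_value = p_val,
                n_permutations = length(perms), seed = seed,
                method = "exact enumeration"))
  }
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(n_permutations), function(k) {
    .anosim_R(ranks, same(sample(grouping)), n)
  }, 0)
  p_val <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_permutations)
  list(statistic = r_obs, p_value = p_val, n_permutations = n_permutations,
       seed = seed, method = "Monte-Carlo permutation")
}

#' Ordinary least squares of abundance on an environmental covariate
#'
#' @param values per-sample abundances (e.g. one genome's RPKM row).
#' @param covariate per-sample environmental values (temperature, depth,
#'   ...); must vary.
#' @return list with `slope`, `intercept`, `p_value` (two-sided t-test on
#'   the slope), `r_squared` and `n`.
#' @export
abundance_regression <- function(values, covariate) {
  stopifnot(length(values) == length(covariate))
  keep <- stats::complete.cases(values, covariate)
  values <- values[keep]; covariate <- covariate[keep]
  if (length(values) < 3) stop("need at least 3 paired observations")
  if (stats::var(covariate) == 0) stop("covariate has zero variance")
  f <- .ols(covariate, values)
  list(slope = f$slope, intercept = f$intercept, p_value = f$p,
       r_squared = f$r2, n = length(values))
}

#' Per-genome abundance-environment regressions
#'
#' Runs [abundance_regression()] on every row of an abundance table. Raw
#' p-values are reported by default, matching common practice of presenting
#' unadjusted per-genome tests; `p_adjust = "BH"` adds a
#' Benjamini-Hochberg column.
#'
#' @param abund genome x sample matrix.
#' @param covariate per-sample values, aligned to columns.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data frame, one row per genome.
#' @export
abundance_regressions <- function(abund, covariate, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  rows <- lapply(rownames(abund), function(g) {
    f <- abundance_regression(abund[g, ], covariate)
    data.frame(genome = g, slope = f$slope, intercept = f$intercept,
               p_value = f$p_value, r_squared = f$r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
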