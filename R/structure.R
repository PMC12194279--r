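#' Nei (1972) standard genetic distance between two frequency tables
#'
#' Computed over the shared loci as `D = -ln(J_ab / sqrt(J_a * J_b))`
#' where the gene identities `J` are ratio-of-sums aggregates over loci
#' and both alleles: `J_a = sum(p_a^2 + q_a^2) / L`, `J_ab =
#' sum(p_a p_b + q_a q_b) / L`.  A pair fixed for opposite alleles at
#' every locus has `J_ab = 0` and `D = Inf` (flagged, not an error).
#'
#' @param freq_a,freq_b `freq_table`s (any source) with >= 1 shared locus.
#' @return The distance (may be `Inf`).
#' @export
nei_distance <- function(freq_a, freq_b) {
  sh <- intersect(freq_a$marker, freq_b$marker)
  if (length(sh) == 0) stop("no shared loci")
  pa <- freq_a$p[match(sh, freq_a$marker)]
  pb <- freq_b$p[match(sh, freq_b$marker)]
  jab <- mean(pa * pb + (1 - pa) * (1 - pb))
  ja <- mean(pa^2 + (1 - pa)^2)
  jb <- mean(pb^2 + (1 - pb)^2)
  if (jab == 0) return(Inf)
  -log(jab / sqrt(ja * jb))
}

#' Rogers distance between two frequency vectors
#'
#' Mean over shared (pairwise-complete) loci of
#' `sqrt(0.5 * sum_alleles (x_u - y_u)^2)`, which for biallelic loci
#' reduces to `|p_x - p_y|`.  Individuals enter as within-individual
#' major-allele frequencies (0, 1/2, 1).
#'
#' @param x,y numeric vectors of per-locus major-allele frequencies,
#'   aligned on the same loci; `NA`s are dropped pairwise.
#' @return The distance in \[0, 1\].
#' @export
rogers_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no shared loci")
  mean(sqrt(0.5 * ((x[ok] - y[ok])^2 + ((1 - x[ok]) - (1 - y[ok]))^2)))
}

#' Labeled distance matrix over frequency tables or unit vectors
#'
#' @param x for `metric = "nei"`: a named list of `freq_table`s; for
#'   `metric = "rogers"`: a units x loci matrix of major-allele
#'   frequencies (individuals coded 0 / 0.5 / 1, `NA` allowed and handled
#'   pairwise-complete).
#' @param metric `"nei"` or `"rogers"`.
#' @return A symmetric matrix with zero diagonal, class `dist_matrix`,
#'   with attribute `metric`.
#' @export
distance_matrix <- function(x, metric = c("nei", "rogers")) {
  metric <- match.arg(metric)
  if (metric == "nei") {
    labels <- names(x)
    n <- length(x)
    d <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- nei_distance(x[[i]], x[[j]])
  } else {
    labels <- rownames(x)
    n <- nrow(x)
    d <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- rogers_distance(x[i, ], x[j, ])
  }
  structure(d, metric = metric, class = c("dist_matrix", "matrix"))
}

# Weir & Cockerham (1984) per-locus variance components for r populations.
# Returns a list of per-locus a, b, c vectors.
wc_components <- function(p_mat, h_mat, n_mat) {
  r <- ncol(p_mat)
  nbar <- rowMeans(n_mat)
  ntot <- rowSums(n_mat)
  nc <- (ntot - rowSums(n_mat^2) / ntot) / (r - 1)
  pbar <- rowSums(n_mat * p_mat) / ntot
  s2 <- rowSums(n_mat * (p_mat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_mat * h_mat) / ntot
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Weir-Cockerham F_ST over two or more accessions
#'
#' The theta estimator of Weir & Cockerham (1984), aggregated as the
#' ratio of summed per-locus `a` components to summed `a + b + c`.
#' Loci monomorphic across all included accessions contribute nothing
#' and are skipped.
#'
#' @param scores a [score_matrix()].
#' @param accessions accessions to include (>= 2); default all.
#' @param markers optional marker restriction.
#' @return The multi-population theta; per-locus sums in attributes.
#' @export
wc_fst <- function(scores, accessions = NULL, markers = NULL) {
  acc <- sample_accessions(scores)
  if (is.null(accessions)) accessions <- unique(acc)
  if (length(accessions) < 2) stop("need at least two accessions")
  g <- unclass(scores)
  if (!is.null(markers)) g <- g[markers, , drop = FALSE]
  p_mat <- h_mat <- n_mat <-
    matrix(0, nrow(g), length(accessions),
           dimnames = list(rownames(g), accessions))
  for (k in seq_along(accessions)) {
    cols <- names(acc)[acc == accessions[k]]
    sub <- g[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    n_mat[, k] <- n
    p_mat[, k] <- 1 - rowSums(sub, na.rm = TRUE) / (2 * n)
    h_mat[, k] <- rowSums(sub == 1L, na.rm = TRUE) / n
  }
  p_mat[n_mat == 0] <- 0
  h_mat[n_mat == 0] <- 0
  ok <- rowSums(n_mat >= 2) == length(accessions)
  pbar <- rowSums(n_mat * p_mat) / rowSums(n_mat)
  ok <- ok & pbar > 0 & pbar < 1
  if (!any(ok)) stop("no usable polymorphic loci")
  comp <- wc_components(p_mat[ok, , drop = FALSE],
                        h_mat[ok, , drop = FALSE],
                        n_mat[ok, , drop = FALSE])
  theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  attr(theta, "n_loci") <- sum(ok)
  theta
}

#' Pairwise Weir-Cockerham F_ST between two accessions
#'
#' @param scores a [score_matrix()].
#' @param accession_a,accession_b the two accessions.
#' @param markers optional marker restriction.
#' @return theta for the pair.
#' @export
pairwise_fst <- function(scores, accession_a, accession_b, markers = NULL) {
  wc_fst(scores, c(accession_a, accession_b), markers)
}

#' Pairwise F_ST matrix over all accessions
#' @inheritParams wc_fst
#' @return A `dist_matrix` of pairwise theta values.
#' @export
fst_matrix <- function(scores, accessions = NULL, markers = NULL) {
  acc <- sample_accessions(scores)
  if (is.null(accessions)) accessions <- unique(acc)
  n <- length(accessions)
  d <- matrix(0, n, n, dimnames = list(accessions, accessions))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- as.numeric(
      pairwise_fst(scores, accessions[i], accessions[j], markers))
  structure(d, metric = "fst", class = c("dist_matrix", "matrix"))
}

# mean squared per-locus frequency difference, pairwise-complete
squared_unit_distances <- function(units) {
  n <- nrow(units)
  d2 <- matrix(0, n, n, dimnames = list(rownames(units), rownames(units)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(units[i, ]) & !is.na(units[j, ])
    if (!any(ok)) stop("units share no loci")
    d2[i, j] <- d2[j, i] <- mean((units[i, ok] - units[j, ok])^2)
  }
  d2
}

#' Analysis of molecular variance (AMOVA)
#'
#' One-level AMOVA partitioning squared Rogers-type distances between
#' units (individuals coded 0 / 0.5 / 1 per locus, or pool-library
#' frequency vectors) into among- and within-accession components, with a
#' permutation p-value obtained by shuffling units among groups.
#'
#' @param units numeric units x loci matrix of major-allele frequencies
#'   (`NA` handled pairwise-complete).
#' @param grouping factor (or vector) of group labels, one per unit.
#' @param n_permutations number of label permutations (default 9999, the
#'   granularity at which p = 1e-4 is resolvable).
#' @param seed optional integer seed for the permutations.
#' @return An object of class `amova_result`: degrees of freedom, sums of
#'   squares, variance components, percent variation and permutation p.
#' @export
amova <- function(units, grouping, n_permutations = 9999, seed = NULL) {
  grouping <- as.factor(grouping)
  stopifnot(nrow(units) == length(grouping))
  if (nlevels(droplevels(grouping)) < 2)
    stop("need at least two groups")
  if (any(table(grouping) < 2))
    stop("every group needs at least two units")
  if (!is.null(seed)) set.seed(seed)
  d2 <- squared_unit_distances(units)
  n <- nrow(units)
  k <- nlevels(grouping)
  ss_from <- function(grp) {
    ss_total <- sum(d2[upper.tri(d2)]) / n
    ss_within <- 0
    for (lev in levels(grp)) {
      idx <- which(grp == lev)
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
    c(among = ss_total - ss_within, within = ss_within)
  }
  ss <- ss_from(grouping)
  df_among <- k - 1
  df_within <- n - k
  ms_among <- ss["among"] / df_among
  sigma_within <- ss["within"] / df_within
  sizes <- as.numeric(table(grouping))
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  sigma_among <- (ms_among - sigma_within) / n0
  total <- sigma_among + sigma_within
  percent <- if (total == 0) c(among = 0, within = 100) else
    100 * c(among = unname(sigma_among), within = unname(sigma_within)) / total
  # permutation test on the among-group variance component
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    gp <- grouping[sample.int(n)]
    ssp <- ss_from(gp)
    sap <- (ssp["among"] / df_among - ssp["within"] / df_within) / n0
    if (sap >= sigma_among) exceed <- exceed + 1L
  }
  p <- (exceed + 1) / (n_permutations + 1)
  structure(list(
    df = c(among = df_among, within = df_within, total = n - 1),
    ss = c(among = unname(ss["among"]), within = unname(ss["within"])),
    sigma = c(among = unname(sigma_among), within = unname(sigma_within)),
    percent = percent,
    p_value = p, n_permutations = n_permutations),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  tab <- data.frame(df = x$df[1:2], SS = x$ss, sigma2 = x$sigma,
                    percent = x$percent)
  print(round(tab, 4))
  cat(sprintf("Total df %d; permutation p = %.4g (%d permutations)\n",
              x$df["total"], x$p_value, x$n_permutations))
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors by
#' the square roots of the positive eigenvalues.  Explained variance
#' fractions are eigenvalues over the sum of positive eigenvalues.
#'
#' @param dist a symmetric distance matrix (e.g. a `dist_matrix`).
#' @param n_dims number of output dimensions (<= units - 1).
#' @return An `mds_result`: `coordinates`, `eigenvalues` (all), and
#'   `explained` (fractions for the returned dimensions).
#' @export
classical_mds <- function(dist, n_dims = 2) {
  d <- as.matrix(dist)
  n <- nrow(d)
  stopifnot(isSymmetric(unname(d)), n_dims >= 1, n_dims <= n - 1)
  if (all(d == 0)) stop("all-zero distance matrix")
  b <- -0.5 * d^2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))
  b <- b + mean(-0.5 * d^2)  # J (-D^2/2) J double-centering
  e <- eigen(b, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  coords <- e$vectors[, seq_len(n_dims), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(n_dims)]), n_dims)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("MDS", seq_len(n_dims))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 explained = pos[seq_len(n_dims)] / sum(pos)),
            class = "mds_result")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a
#' permutation p-value from simultaneous row/column permutations of the
#' second matrix (one-sided, greater).
#'
#' @param d1,d2 symmetric matrices with identical labels in the same
#'   order.
#' @param n_permutations number of permutations.
#' @param seed optional integer seed.
#' @return List with `r`, `p_value`, `n_permutations`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dimnames(d1), dimnames(d2)) ||
      !identical(dim(d1), dim(d2)))
    stop("distance matrices must share labels and order")
  n <- nrow(d1)
  if (n < 3) stop("need at least 3 units")
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(d1)
  r_obs <- stats::cor(d1[ut], d2[ut])
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(n)
    if (stats::cor(d1[ut], d2[idx, idx][ut]) >= r_obs)
      exceed <- exceed + 1L
  }
  list(r = r_obs, p_value = (exceed + 1) / (n_permutations + 1),
       n_permutations = n_permutations)
}

#' Major-allele frequency encoding of individuals for distance analyses
#'
#' Converts genotype codes to within-individual major-allele frequencies
#' (0 -> 1, 1 -> 0.5, 2 -> 0), yielding a units x loci matrix suitable
#' for [distance_matrix()] (Rogers) and [amova()].
#'
#' @param scores a [score_matrix()].
#' @param samples optional sample ids to include.
#' @param markers optional marker restriction.
#' @return Numeric matrix, samples as rows.
#' @export
genotype_frequency_units <- function(scores, samples = NULL,
                                     markers = NULL) {
  g <- unclass(scores)
  if (!is.null(samples)) g <- g[, samples, drop = FALSE]
  if (!is.null(markers)) g <- g[markers, , drop = FALSE]
  t((2 - g) / 2)
}
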