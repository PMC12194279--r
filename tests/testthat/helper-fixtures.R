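# Shared fixtures and independent oracles for the test suite.

# a tiny hand-built score matrix: 4 markers x 5 samples, two accessions
tiny_scores <- function() {
  g <- matrix(c(0L, 1L, 1L, 2L, NA,
                0L, 0L, 0L, 0L, 0L,
                2L, 2L, 1L, NA, NA,
                1L, 1L, 1L, 1L, 1L),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("M", 1:4),
                              c("A_001", "A_002", "A_003", "B_001",
                                "B_002")))
  score_matrix(g, c(A_001 = "A", A_002 = "A", A_003 = "A",
                    B_001 = "B", B_002 = "B"))
}

# construct a true_frequencies object by hand
manual_truth <- function(p_by_accession) {
  ap <- do.call(cbind, p_by_accession)
  rownames(ap) <- sprintf("M%06d", seq_len(nrow(ap)))
  structure(list(
    ancestral_p = stats::setNames(rowMeans(ap), rownames(ap)),
    accession_p = ap), class = "true_frequencies")
}

# small fast config for smoke-level pipeline tests
small_config <- function(seed = 1, ...) {
  sim_config(n_accessions = 2, n_markers = 300,
             pool_sizes = c(20, 40), seed = seed, ...)
}

# --- independent oracles ---------------------------------------------------

# Lin's CCC by direct transcription of the defining formula
oracle_ccc <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# Weir-Cockerham theta via an explicit per-locus scalar loop over genotype
# count tables (pops x {hom-major, het, hom-minor}), one list entry per locus
oracle_wc_theta <- function(loci) {
  num <- den <- 0
  for (tab in loci) {
    r <- nrow(tab)
    n <- rowSums(tab)
    p <- (tab[, 1] + 0.5 * tab[, 2]) / n
    h <- tab[, 2] / n
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# exhaustive rarefaction: average number of distinct alleles over all
# C(N, g) subsamples of the gene-copy pool (N <= 8 in tests)
oracle_rarefaction <- function(n_major, n_minor, g) {
  pool <- c(rep(1L, n_major), rep(0L, n_minor))
  subs <- utils::combn(length(pool), g)
  mean(apply(subs, 2, function(idx) length(unique(pool[idx]))))
}

# genotype-count table for one locus from a score matrix subset
locus_counts <- function(scores, samples, marker) {
  g <- unclass(scores)[marker, samples]
  c(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
    sum(g == 2L, na.rm = TRUE))
}
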