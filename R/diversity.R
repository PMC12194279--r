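#' Observed heterozygosity from individual scores
#'
#' Per retained locus, the fraction of heterozygous calls among
#' non-missing subset members; summarised as the mean over loci.
#'
#' @param scores a [score_matrix()].
#' @param accession accession id.
#' @param subset optional sample ids (defaults to the accession's
#'   samples).
#' @param markers optional marker ids to restrict to (e.g. the filtered
#'   set); defaults to all markers with at least one call.
#' @return List with `per_locus` (named vector) and `mean`.
#' @export
observed_heterozygosity <- function(scores, accession, subset = NULL,
                                    markers = NULL) {
  acc <- sample_accessions(scores)
  acc_samples <- names(acc)[acc == accession]
  if (length(acc_samples) == 0) stop("unknown accession: ", accession)
  if (is.null(subset)) subset <- acc_samples
  g <- unclass(scores)[, subset, drop = FALSE]
  if (!is.null(markers)) g <- g[markers, , drop = FALSE]
  n <- rowSums(!is.na(g))
  if (all(n == 0)) stop("no loci with data")
  ho <- rowSums(g == 1L, na.rm = TRUE) / n
  ho <- ho[n > 0]
  list(per_locus = ho, mean = mean(ho))
}

#' Expected heterozygosity from a frequency table
#'
#' Per locus `H_E = 1 - p^2 - q^2 = 2pq`; the same formula serves
#' individual- and pool-derived frequencies.
#'
#' @param freq_table a `freq_table`.
#' @return List with `per_locus` (named vector) and `mean`.
#' @export
expected_heterozygosity <- function(freq_table) {
  he <- 1 - freq_table$p^2 - freq_table$q^2
  names(he) <- freq_table$marker
  list(per_locus = he, mean = mean(he))
}

#' Inbreeding coefficient from observed and expected heterozygosity
#'
#' Default convention is the ratio of means, `F_IS = 1 - mean(H_O) /
#' mean(H_E)`; the per-locus alternative `mean(1 - H_O/H_E)` is exposed
#' via `method = "mean-of-ratios"` (loci with `H_E = 0` are dropped
#' there).
#'
#' @param ho,he numeric vectors (or scalars) of observed and expected
#'   heterozygosities on the same loci.
#' @param method aggregation convention.
#' @return F_IS (scalar).
#' @export
inbreeding_coefficient <- function(ho, he,
                                   method = c("ratio-of-means",
                                              "mean-of-ratios")) {
  method <- match.arg(method)
  if (method == "ratio-of-means") {
    if (mean(he) == 0) stop("mean expected heterozygosity is zero")
    1 - mean(ho) / mean(he)
  } else {
    ok <- he > 0
    if (!any(ok)) stop("all loci have zero expected heterozygosity")
    mean(1 - ho[ok] / he[ok])
  }
}

#' Rarefaction allelic richness from individual scores
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' gene copies, per locus:
#' `AR(g) = sum_alleles (1 - choose(N - N_allele, g) / choose(N, g))`
#' with `N` the non-missing gene copies at the locus (2 per individual)
#' and `N_allele` the copies of each allele.  Loci with fewer than `g`
#' copies are excluded (ids recorded in the `excluded` attribute of the
#' result).
#'
#' @param scores a [score_matrix()].
#' @param accession accession id.
#' @param subset optional sample ids.
#' @param markers optional marker restriction.
#' @param g rarefaction size in gene copies (>= 2); defaults to twice the
#'   minimum number of non-missing individuals over loci.
#' @return List with `per_locus`, `mean`, `g` and `excluded`.
#' @export
allelic_richness_rarefaction <- function(scores, accession, subset = NULL,
                                         markers = NULL, g = NULL) {
  acc <- sample_accessions(scores)
  acc_samples <- names(acc)[acc == accession]
  if (length(acc_samples) == 0) stop("unknown accession: ", accession)
  if (is.null(subset)) subset <- acc_samples
  gm <- unclass(scores)[, subset, drop = FALSE]
  if (!is.null(markers)) gm <- gm[markers, , drop = FALSE]
  n_ind <- rowSums(!is.na(gm))
  N <- 2 * n_ind
  n_minor <- rowSums(gm, na.rm = TRUE)       # copies of the minor allele
  n_major <- N - n_minor
  if (is.null(g)) g <- 2 * min(n_ind[n_ind > 0])
  if (g < 2) stop("rarefaction size g must be at least 2")
  ok <- N >= g
  # P(allele absent from a subsample of g copies) = C(N - N_a, g) / C(N, g)
  p_absent <- function(n_allele, N) {
    exp(lchoose(N - n_allele, g) - lchoose(N, g))
  }
  ar <- (1 - p_absent(n_major[ok], N[ok])) +
    (1 - p_absent(n_minor[ok], N[ok]))
  names(ar) <- rownames(gm)[ok]
  list(per_locus = ar, mean = mean(ar), g = g,
       excluded = rownames(gm)[!ok])
}

#' Effective number of alleles from pooled frequencies
#'
#' Per locus `Ae = 1 / (p^2 + q^2)`, the allele count of a locus with
#' equally frequent alleles and the same homozygosity.  This is the
#' pool-side counterpart of rarefaction richness; the two are related but
#' not numerically comparable, so the package labels them distinctly.
#'
#' @param freq_table a `freq_table`.
#' @return List with `per_locus` and `mean`.
#' @export
effective_alleles_pool <- function(freq_table) {
  ae <- 1 / (freq_table$p^2 + freq_table$q^2)
  names(ae) <- freq_table$marker
  list(per_locus = ae, mean = mean(ae))
}

#' Within-accession diversity record from individual data
#'
#' Applies the filters, then assembles the ind-seq diversity statistics:
#' polymorphic SNP count (filtered markers with both alleles observed),
#' mean observed and expected heterozygosity, F_IS (ratio-of-means) and
#' rarefaction allelic richness.
#'
#' @param scores a [score_matrix()].
#' @param accession accession id.
#' @param subset optional sample ids.
#' @param settings a [filter_settings()]; the study's ind-seq defaults.
#' @param g optional rarefaction size passed through.
#' @return One-row data frame (`accession`, `source`, `size`, `n_snps`,
#'   `ho`, `he`, `fis`, `ae`).
#' @export
diversity_ind <- function(scores, accession, subset = NULL,
                          settings = filter_settings(0.10, 0.05),
                          g = NULL) {
  acc <- sample_accessions(scores)
  if (is.null(subset)) subset <- names(acc)[acc == accession]
  mf <- marker_missing_fraction(scores, subset)
  tab <- apply_filters(ind_allele_frequencies(scores, accession, subset),
                       mf, settings)
  poly <- tab$marker[pmin(tab$p, tab$q) > 0]
  ho <- observed_heterozygosity(scores, accession, subset, markers = poly)
  he <- expected_heterozygosity(tab[tab$marker %in% poly, , drop = FALSE])
  ar <- allelic_richness_rarefaction(scores, accession, subset,
                                     markers = poly, g = g)
  data.frame(accession = accession, source = "ind",
             size = length(subset), depth = NA_real_,
             n_snps = length(poly), ho = ho$mean, he = he$mean,
             fis = inbreeding_coefficient(ho$mean, he$mean),
             ae = ar$mean, stringsAsFactors = FALSE)
}

#' Within-accession diversity record from pooled data
#'
#' Merges the pool libraries at the requested depth, applies the filters
#' (the study's pool-seq defaults: MD < 10%, MAF > 0.01), and assembles
#' the pool-side statistics: SNP count, mean expected heterozygosity and
#' effective alleles.
#'
#' @param counts a [count_matrix()].
#' @param design the `pool_design`.
#' @param accession,size,depth pool identity and merged depth.
#' @param settings a [filter_settings()].
#' @return One-row data frame matching [diversity_ind()] (with `ho` and
#'   `fis` set to `NA`: pools carry no genotype-level information).
#' @export
diversity_pool <- function(counts, design, accession, size, depth,
                           settings = filter_settings(0.10, 0.01)) {
  merged <- merge_pool_replicates(counts, design, accession, size, depth)
  mf <- marker_missing_fraction(counts, attr(merged, "library_ids"))
  tab <- apply_filters(pool_allele_frequencies(merged, accession, size,
                                               depth),
                       mf, settings)
  poly <- tab[pmin(tab$p, tab$q) > 0, , drop = FALSE]
  he <- expected_heterozygosity(poly)
  ae <- effective_alleles_pool(poly)
  data.frame(accession = accession, source = "pool",
             size = size, depth = depth,
             n_snps = nrow(poly), ho = NA_real_, he = he$mean,
             fis = NA_real_, ae = ae$mean, stringsAsFactors = FALSE)
}

#' Difference in expected heterozygosity, pool minus individual
#'
#' One record per (accession, size, depth) cell:
#' `delta = H_E(pool, a, s, j) - H_E(ind, a, s)`.
#'
#' @param ind_records data frame of ind-seq diversity records
#'   (from [diversity_ind()]).
#' @param pool_records data frame of pool-seq diversity records.
#' @return Data frame with `accession`, `size`, `depth`, `he_pool`,
#'   `he_ind`, `delta`; pool cells without a matching ind cell are
#'   flagged in column `flag`.
#' @export
delta_he <- function(ind_records, pool_records) {
  key_ind <- paste(ind_records$accession, ind_records$size)
  out <- pool_records[, c("accession", "size", "depth")]
  out$he_pool <- pool_records$he
  i <- match(paste(out$accession, out$size), key_ind)
  out$he_ind <- ind_records$he[i]
  out$delta <- out$he_pool - out$he_ind
  out$flag <- ifelse(is.na(i), "no_matching_ind_cell", "")
  rownames(out) <- NULL
  out
}
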