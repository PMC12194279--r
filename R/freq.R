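#' Per-marker missing-data fraction within a sample group
#'
#' For individual score data, a marker's missing fraction is the share of
#' group samples whose genotype call is missing; for pooled count data it
#' is the share of group pool-library samples with a `(0, 0)` read-count
#' pair (no coverage).
#'
#' @param x a [score_matrix()] or [count_matrix()].
#' @param group_samples character vector of column ids defining the
#'   group; must be nonempty.
#' @return Named numeric vector of per-marker missing fractions.
#' @export
marker_missing_fraction <- function(x, group_samples) {
  if (length(group_samples) == 0) stop("group must be nonempty")
  if (inherits(x, "count_matrix")) {
    if (!all(group_samples %in% colnames(x$major)))
      stop("unknown pool samples in group")
    miss <- (x$major + x$minor)[, group_samples, drop = FALSE] == 0
  } else {
    if (!all(group_samples %in% colnames(x)))
      stop("unknown samples in group")
    miss <- is.na(unclass(x)[, group_samples, drop = FALSE])
  }
  rowMeans(miss)
}

#' Allele frequencies from individual genotype scores
#'
#' For each marker, the major-allele frequency over the non-missing
#' members of the subset is `p = (AA + Aa/2) / (AA + Aa + aa)`, where AA,
#' Aa and aa count homozygous-major, heterozygous and homozygous-minor
#' individuals.  Markers at which every subset member is missing are
#' excluded from the table; their ids are recorded in the `excluded`
#' attribute.
#'
#' @param scores a [score_matrix()].
#' @param accession accession whose samples are used.
#' @param subset optional character vector of sample ids (must belong to
#'   the accession); defaults to all of the accession's samples.
#' @return An unfiltered `freq_table` with columns `marker`, `p`, `q`,
#'   `n_used`.
#' @export
ind_allele_frequencies <- function(scores, accession, subset = NULL) {
  acc <- sample_accessions(scores)
  acc_samples <- names(acc)[acc == accession]
  if (length(acc_samples) == 0) stop("unknown accession: ", accession)
  if (is.null(subset)) subset <- acc_samples
  if (!all(subset %in% acc_samples))
    stop("subset contains samples outside accession ", accession)
  g <- unclass(scores)[, subset, drop = FALSE]
  n_used <- rowSums(!is.na(g))
  # genotype code is the minor-allele dosage, so p = 1 - mean(code)/2
  p <- 1 - rowSums(g, na.rm = TRUE) / (2 * n_used)
  keep <- n_used > 0
  new_freq_table(rownames(g)[keep], p[keep], n_used[keep],
                 accession = accession, source = "ind",
                 size = length(subset),
                 excluded = rownames(g)[!keep])
}

# merged analysis depths implied by the two per-library depth classes
merged_depth_levels <- function(depth_classes) {
  d <- sort(unique(depth_classes))
  if (length(d) != 2)
    stop("replicate merging expects exactly two library depth classes")
  c(2 * d[1], 2 * d[2], 2 * (d[1] + d[2]))
}

#' Merge pooled-library replicates into an analysis depth
#'
#' The two tissue replicates of an (accession, size) pool are each
#' sequenced as two libraries of different depth classes.  Analysis
#' depths are formed by elementwise summation of read counts: the lowest
#' merged depth sums the two low-class libraries, the middle one the two
#' high-class libraries, and the highest consolidates all four (with the
#' default 0.9/1.5 Mr classes: 1.8, 3.0 and 4.8 Mr).
#'
#' @param counts a [count_matrix()] of pooled libraries.
#' @param design the matching `pool_design`.
#' @param accession,size pool identity.
#' @param depth_level one of the merged depths implied by the design's
#'   depth classes (default classes: 1.8, 3.0 or 4.8).
#' @return A one-column [count_matrix()] of merged counts.
#' @export
merge_pool_replicates <- function(counts, design, accession, size,
                                  depth_level) {
  rows <- design[design$accession == accession & design$size == size, ]
  if (nrow(rows) == 0)
    stop(sprintf("no pool libraries for accession %s at size %d",
                 accession, size))
  levels <- merged_depth_levels(rows$depth_class)
  i <- which(abs(levels - depth_level) < 1e-9)
  if (length(i) != 1)
    stop(sprintf("depth_level %g is not one of the merged depths (%s)",
                 depth_level, paste(signif(levels, 3), collapse = ", ")))
  classes <- sort(unique(rows$depth_class))
  use <- switch(i,
                rows$depth_class == classes[1],
                rows$depth_class == classes[2],
                rep(TRUE, nrow(rows)))
  ids <- rows$pool_sample_id[use]
  expected <- if (i == 3) 2 * length(unique(rows$tissue_rep)) else
    length(unique(rows$tissue_rep))
  if (length(ids) != expected)
    stop("missing replicate/library for the requested combination")
  nA <- rowSums(counts$major[, ids, drop = FALSE])
  na <- rowSums(counts$minor[, ids, drop = FALSE])
  id <- sprintf("%s_s%02d_d%g", accession, size, depth_level)
  out <- count_matrix(matrix(as.integer(nA), ncol = 1,
                             dimnames = list(names(nA), id)),
                      matrix(as.integer(na), ncol = 1,
                             dimnames = list(names(na), id)))
  attr(out, "library_ids") <- ids
  out
}

#' Allele frequencies from merged pooled read counts
#'
#' Per marker, `p = n_A / (n_A + n_a)` over the merged counts; markers
#' with zero total reads are excluded as missing (ids recorded in the
#' `excluded` attribute).
#'
#' @param merged a one-column [count_matrix()] from
#'   [merge_pool_replicates()].
#' @param accession,size,depth metadata recorded on the table.
#' @return An unfiltered `freq_table` (column `n_used` holds total reads).
#' @export
pool_allele_frequencies <- function(merged, accession, size, depth) {
  nA <- merged$major[, 1]
  na <- merged$minor[, 1]
  tot <- nA + na
  keep <- tot > 0
  new_freq_table(rownames(merged$major)[keep],
                 nA[keep] / tot[keep], tot[keep],
                 accession = accession, source = "pool",
                 size = size, depth = depth,
                 excluded = rownames(merged$major)[!keep])
}

#' Apply missing-data and minor-allele-frequency filters
#'
#' A marker is retained iff its missing fraction is strictly below
#' `settings$md_max` and its minor-allele frequency `min(p, 1 - p)` is
#' strictly above `settings$maf_min` — a marker whose MAF equals the
#' threshold is discarded.  Counts of markers dropped by each rule are
#' attached as attributes `dropped_md` and `dropped_maf` (a marker
#' failing both is counted under MD).
#'
#' @param table an unfiltered `freq_table`.
#' @param missing_fractions named per-marker missing fractions computed
#'   on the same sample group (see [marker_missing_fraction()]).
#' @param settings a [filter_settings()].
#' @return The filtered `freq_table`.
#' @export
apply_filters <- function(table, missing_fractions, settings) {
  stopifnot(inherits(settings, "filter_settings"))
  mf <- missing_fractions[table$marker]
  if (anyNA(mf))
    stop("missing_fractions must cover every marker in the table")
  # 1e-9 guards absorb floating-point wobble at the threshold (e.g.
  # 1 - 0.95 > 0.05 in doubles) so boundary markers are dropped as stated
  pass_md <- mf < settings$md_max - 1e-9
  maf <- pmin(table$p, table$q)
  pass_maf <- maf > settings$maf_min + 1e-9
  out <- table[pass_md & pass_maf, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("accession", "source", "size", "depth", "excluded"))
    attr(out, a) <- attr(table, a)
  attr(out, "settings") <- settings
  attr(out, "dropped_md") <- sum(!pass_md)
  attr(out, "dropped_maf") <- sum(pass_md & !pass_maf)
  class(out) <- class(table)
  out
}
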