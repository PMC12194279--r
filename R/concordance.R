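#' Markers shared between individual and pooled frequency tables
#'
#' @param ind_table,pool_table filtered `freq_table`s for the same
#'   accession and sample size.
#' @return Character vector of shared marker ids.
#' @export
shared_snps <- function(ind_table, pool_table) {
  if (!identical(attr(ind_table, "accession"), attr(pool_table, "accession")))
    stop("tables come from different accessions")
  intersect(ind_table$marker, pool_table$marker)
}

#' Representativity of a pooled SNP set
#'
#' The percentage of the individually detected SNPs that are also
#' retained in the matched pooled dataset.
#'
#' @param n_shared number of shared markers.
#' @param n_ind_snps number of markers retained in the individual data.
#' @return Percentage in \[0, 100\]; `NA` (flagged) when `n_ind_snps` is 0.
#' @export
representativity <- function(n_shared, n_ind_snps) {
  if (n_ind_snps == 0) return(NA_real_)
  100 * n_shared / n_ind_snps
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two measurement series with the 45-degree identity line:
#' `CCC = 2*cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with
#' population moments (denominator `n`, Lin's original estimator).  An
#' optional confidence interval uses the Fisher z-transformation with
#' Lin's asymptotic variance.
#'
#' @param x,y numeric vectors of paired frequencies, length >= 3.
#' @param ci if `TRUE`, attach a `conf.int` attribute.
#' @param conf_level confidence level for the interval.
#' @return The CCC; `NA` when both series are constant (undefined).
#' @export
concordance_correlation <- function(x, y, ci = FALSE, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in paired frequencies")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (vx == 0 && vy == 0) return(NA_real_)  # both series constant: undefined
  ccc <- 2 * sxy / (vx + vy + (mx - my)^2)
  if (ci && vx > 0 && vy > 0 && abs(ccc) < 1) {
    r <- sxy / sqrt(vx * vy)
    u <- (mx - my) / sqrt(sqrt(vx * vy))
    z <- atanh(ccc)
    vz <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
             2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
             ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    half <- stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(max(vz, 0))
    attr(ccc, "conf.int") <- tanh(c(z - half, z + half))
  }
  ccc
}

#' Factorial sweep of Representativity and CCC
#'
#' Runs the full comparison grid between individual and pooled allele
#' frequencies: for every accession `a`, pool size `s`, missing-data
#' threshold `m`, merged pool depth `j` and pool MAF threshold `k`, both
#' sides are filtered (individual MAF fixed, by default at 0.05), their
#' retained marker sets intersected, and Representativity and Lin's CCC
#' computed on the shared markers.  The individual subset at size `s` is
#' the pool's recorded membership — the same plants feed both estimates.
#' Missing-data fractions are computed on the individual subset for the
#' ind side and across the libraries merged into depth `j` for the pool
#' side.  Cells with fewer than 3 shared markers (or an empty side) are
#' flagged, never dropped.
#'
#' @param scores a [score_matrix()] (with missingness applied).
#' @param counts the matching pooled [count_matrix()].
#' @param design the `pool_design`.
#' @param md_grid missing-data thresholds `m`.
#' @param depths merged pool depths `j`; default derived from the design.
#' @param pool_mafs pool-side MAF thresholds `k`.
#' @param ind_maf fixed individual-side MAF threshold.
#' @param sizes pool sizes to sweep; default all sizes in the design.
#' @param accessions accessions to sweep; default all in the design.
#' @return Data frame of one record per grid cell with columns
#'   `accession`, `size`, `md_max`, `depth`, `pool_maf`, `n_ind_snps`,
#'   `n_pool_snps`, `n_shared`, `representativity`, `ccc`, `flag`.
#' @export
concordance_sweep <- function(scores, counts, design,
                              md_grid = seq(0.1, 0.6, by = 0.1),
                              depths = NULL,
                              pool_mafs = c(0.01, 0.05),
                              ind_maf = 0.05,
                              sizes = NULL,
                              accessions = NULL) {
  if (is.null(sizes)) sizes <- sort(unique(design$size))
  if (is.null(accessions)) accessions <- unique(design$accession)
  if (is.null(depths)) depths <- merged_depth_levels(design$depth_class)
  out <- vector("list",
                length(accessions) * length(sizes) * length(md_grid) *
                  length(depths) * length(pool_mafs))
  ii <- 0L
  for (a in accessions) {
    for (s in sizes) {
      members <- pool_members(design, a, s)
      ind_mf <- marker_missing_fraction(scores, members)
      ind_raw <- ind_allele_frequencies(scores, a, members)
      for (j in depths) {
        merged <- merge_pool_replicates(counts, design, a, s, j)
        libs <- attr(merged, "library_ids")
        pool_mf <- marker_missing_fraction(counts, libs)
        pool_raw <- pool_allele_frequencies(merged, a, s, j)
        for (m in md_grid) {
          ind_tab <- apply_filters(ind_raw, ind_mf,
                                   filter_settings(m, ind_maf))
          for (k in pool_mafs) {
            pool_tab <- apply_filters(pool_raw, pool_mf,
                                      filter_settings(m, k))
            sh <- shared_snps(ind_tab, pool_tab)
            flag <- ""
            ccc <- NA_real_
            if (nrow(ind_tab) == 0) {
              flag <- "no_ind_snps"
            } else if (length(sh) < 3) {
              flag <- "lt3_shared"
            } else {
              x <- ind_tab$p[match(sh, ind_tab$marker)]
              y <- pool_tab$p[match(sh, pool_tab$marker)]
              ccc <- concordance_correlation(x, y)
              if (is.na(ccc)) flag <- "constant_series"
            }
            ii <- ii + 1L
            out[[ii]] <- data.frame(
              accession = a, size = s, md_max = m, depth = j,
              pool_maf = k,
              n_ind_snps = nrow(ind_tab), n_pool_snps = nrow(pool_tab),
              n_shared = length(sh),
              representativity = representativity(length(sh),
                                                  nrow(ind_tab)),
              ccc = as.numeric(ccc), flag = flag,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
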