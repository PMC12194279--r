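#' Construct a score matrix of individual genotype calls
#'
#' A score matrix holds biallelic genotype codes for markers (rows) by
#' individual samples (columns).  Codes follow the DArT-style convention
#' used throughout the package: `0` = homozygous for the major allele,
#' `1` = heterozygous, `2` = homozygous for the minor allele, `NA` =
#' missing call.  "Major" is fixed per marker when the data are generated
#' or called, and is shared with the corresponding count report so that
#' individual- and pool-derived frequencies are polarised identically.
#'
#' @param genotypes integer matrix (markers x samples) with values in
#'   `c(0L, 1L, 2L, NA)`; must carry rownames (marker ids) and colnames
#'   (sample ids).
#' @param accessions named character vector mapping every sample id to
#'   its accession.
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(genotypes, accessions) {
  if (!is.matrix(genotypes)) stop("genotypes must be a matrix")
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop("genotypes must have marker rownames and sample colnames")
  if (anyDuplicated(rownames(genotypes)))
    stop("duplicate marker ids in score matrix")
  if (anyDuplicated(colnames(genotypes)))
    stop("duplicate sample ids in score matrix")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  samples <- colnames(genotypes)
  if (!all(samples %in% names(accessions)))
    stop("every sample must map to an accession")
  storage.mode(genotypes) <- "integer"
  structure(genotypes,
            accessions = accessions[samples],
            class = c("score_matrix", "matrix"))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d markers x %d samples, %d accessions, %.1f%% missing\n",
              nrow(x), ncol(x),
              length(unique(attr(x, "accessions"))),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Accession labels of the samples in a score matrix
#' @param scores a [score_matrix()].
#' @return named character vector, one entry per sample column.
#' @export
sample_accessions <- function(scores) attr(scores, "accessions")

#' Construct a count matrix of pooled allele read counts
#'
#' Holds, for every marker (row) and pooled-library sample (column), the
#' number of reads supporting the major (`major`) and minor (`minor`)
#' allele.  A `(0, 0)` pair means the marker received no coverage in that
#' library and is treated as missing downstream.
#'
#' @param major,minor nonnegative integer matrices of identical dimension
#'   and dimnames (markers x pool samples).
#' @return An object of class `count_matrix` (a list with elements
#'   `major` and `minor`).
#' @export
count_matrix <- function(major, minor) {
  if (!is.matrix(major) || !is.matrix(minor))
    stop("major and minor must be matrices")
  if (!identical(dim(major), dim(minor)) ||
      !identical(dimnames(major), dimnames(minor)))
    stop("major and minor matrices must share dimensions and dimnames")
  if (is.null(rownames(major)) || is.null(colnames(major)))
    stop("count matrices must have marker rownames and sample colnames")
  if (anyDuplicated(rownames(major))) stop("duplicate marker ids")
  if (any(major < 0, na.rm = TRUE) || any(minor < 0, na.rm = TRUE))
    stop("read counts must be nonnegative")
  storage.mode(major) <- "integer"
  storage.mode(minor) <- "integer"
  structure(list(major = major, minor = minor), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d markers x %d pool samples, %.1f%% zero-coverage\n",
              nrow(x$major), ncol(x$major),
              100 * mean(x$major + x$minor == 0)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$major)

#' Marker ids of a score or count matrix
#' @param x a `score_matrix` or `count_matrix`.
#' @return character vector of marker ids.
#' @export
marker_ids <- function(x) {
  if (inherits(x, "count_matrix")) rownames(x$major) else rownames(x)
}

#' Filter settings for marker retention
#'
#' @param md_max maximum missing-data fraction; markers are retained when
#'   their missing fraction is strictly below `md_max`.
#' @param maf_min minimum minor-allele frequency; markers are retained
#'   when `min(p, 1 - p)` is strictly above `maf_min` (a marker at
#'   exactly the threshold is discarded).
#' @return An object of class `filter_settings`.
#' @export
filter_settings <- function(md_max = 0.10, maf_min = 0.05) {
  stopifnot(is.numeric(md_max), length(md_max) == 1,
            md_max > 0, md_max < 1,
            is.numeric(maf_min), length(maf_min) == 1,
            maf_min >= 0, maf_min < 0.5)
  structure(list(md_max = md_max, maf_min = maf_min),
            class = "filter_settings")
}

# internal constructor for per-accession frequency tables
new_freq_table <- function(marker, p, n_used, accession, source,
                           size = NA_integer_, depth = NA_real_,
                           excluded = character(0)) {
  stopifnot(length(marker) == length(p), length(p) == length(n_used))
  df <- data.frame(marker = marker, p = p, q = 1 - p, n_used = n_used,
                   stringsAsFactors = FALSE)
  structure(df,
            accession = accession, source = source, size = size,
            depth = depth, excluded = excluded,
            class = c("freq_table", "data.frame"))
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table (%s, accession %s, s=%s%s): %d markers\n",
              attr(x, "source"), attr(x, "accession"),
              attr(x, "size"),
              if (is.na(attr(x, "depth"))) "" else
                sprintf(", depth=%g Mr", attr(x, "depth")),
              nrow(x)))
  NextMethod()
}
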