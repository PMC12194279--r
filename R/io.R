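#' Read and write DArT-style SNP score reports
#'
#' The score report is a plain CSV: a header row of sample ids with a
#' leading `marker_id` column, and one row per marker whose cells are
#' `0` (homozygous major), `1` (heterozygous), `2` (homozygous minor) or
#' `"-"` (missing).  Metadata columns of vendor reports are not
#' reproduced; any malformed cell or duplicated marker is a hard error
#' rather than a silent coercion.
#'
#' @param path file path.
#' @param accessions optional named character vector mapping sample ids
#'   to accessions.  When `NULL`, accessions are inferred from sample ids
#'   of the form `<accession>_<number>`; ids without that shape all fall
#'   into a single accession `"ALL"`.
#' @return A [score_matrix()].
#' @export
read_score_report <- function(path, accessions = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "marker_id")
    stop("score report must start with a marker_id column")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated marker id in score report: ", dup[1])
  samples <- names(df)[-1]
  cells <- as.matrix(df[, -1, drop = FALSE])
  ok <- cells %in% c("0", "1", "2", "-")
  if (!all(ok)) {
    idx <- which(!ok)[1]
    r <- (idx - 1) %% nrow(cells) + 1
    c <- (idx - 1) %/% nrow(cells) + 1
    stop(sprintf("unknown genotype token '%s' at marker %s, sample %s",
                 cells[idx], ids[r], samples[c]))
  }
  g <- matrix(NA_integer_, nrow = nrow(cells), ncol = ncol(cells),
              dimnames = list(ids, samples))
  g[cells != "-"] <- as.integer(cells[cells != "-"])
  if (is.null(accessions)) {
    pref <- sub("_[0-9]+$", "", samples)
    if (all(pref != samples)) {
      accessions <- stats::setNames(pref, samples)
    } else {
      accessions <- stats::setNames(rep("ALL", length(samples)), samples)
    }
  }
  score_matrix(g, accessions)
}

#' @rdname read_score_report
#' @param scores a [score_matrix()] to serialise.
#' @export
write_score_report <- function(scores, path) {
  g <- unclass(scores)
  cells <- matrix(as.character(g), nrow = nrow(g))
  cells[is.na(g)] <- "-"
  df <- data.frame(marker_id = rownames(g), cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("marker_id", colnames(g))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write DArT-style allele count reports
#'
#' The count report is a CSV with two rows per marker: both carry the
#' marker id in the first column, an allele tag (`Ref` for the major
#' allele, `Alt` for the minor) in the second, and nonnegative integer
#' read counts for each pooled-library sample.  A marker must contribute
#' exactly a `Ref`/`Alt` row pair; negative counts and unpaired rows are
#' hard errors.
#'
#' @param path file path.
#' @return A [count_matrix()].
#' @export
read_count_report <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1:2], c("marker_id", "allele")))
    stop("count report must start with marker_id and allele columns")
  if (nrow(df) %% 2 != 0)
    stop("count report must contain two rows per marker")
  ref <- df[df$allele == "Ref", , drop = FALSE]
  alt <- df[df$allele == "Alt", , drop = FALSE]
  if (nrow(ref) != nrow(alt) || !identical(ref$marker_id, alt$marker_id))
    stop("each marker needs one Ref and one Alt row, in order")
  if (anyDuplicated(ref$marker_id))
    stop("duplicated marker id in count report: ",
         ref$marker_id[duplicated(ref$marker_id)][1])
  to_mat <- function(d) {
    m <- as.matrix(d[, -(1:2), drop = FALSE])
    if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
      stop("read counts must be nonnegative integers")
    rownames(m) <- d$marker_id
    m
  }
  count_matrix(to_mat(ref), to_mat(alt))
}

#' @rdname read_count_report
#' @param counts a [count_matrix()] to serialise.
#' @export
write_count_report <- function(counts, path) {
  m <- nrow(counts$major)
  idx <- rep(seq_len(m), each = 2)
  out <- matrix(0L, nrow = 2 * m, ncol = ncol(counts$major))
  out[seq(1, 2 * m, 2), ] <- counts$major
  out[seq(2, 2 * m, 2), ] <- counts$minor
  df <- data.frame(marker_id = rownames(counts$major)[idx],
                   allele = rep(c("Ref", "Alt"), m),
                   out, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("marker_id", "allele", colnames(counts$major))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the pool design map
#'
#' CSV with columns `pool_sample_id`, `accession`, `size`, `tissue_rep`,
#' `depth_class`, `member_ids` (semicolon-joined individual ids).
#'
#' @param path file path.
#' @return A `pool_design` data frame.
#' @export
read_pool_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pool_sample_id", "accession", "size", "tissue_rep",
            "depth_class", "member_ids")
  if (!all(need %in% names(df)))
    stop("design map must contain columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  structure(df, class = c("pool_design", "data.frame"))
}

#' @rdname read_pool_design
#' @param design a `pool_design` to serialise.
#' @export
write_pool_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
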