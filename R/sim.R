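#' Simulation configuration for a nested pooling experiment
#'
#' Defines the world the synthetic-data generator draws from: a set of
#' divergent accessions (Balding-Nichols drift around an ancestral allele
#' frequency), inbred individuals within each accession, marker-level
#' missingness in the individual score data, and a nested pool design in
#' which each accession contributes pools of increasing size, each pool
#' made as two tissue replicates sequenced as two libraries of different
#' read-depth classes.
#'
#' @param n_accessions number of accessions (populations).
#' @param n_markers number of biallelic markers to simulate.
#' @param n_individuals_per_accession individuals genotyped per accession.
#' @param divergence_theta Balding-Nichols drift parameter in (0, 1);
#'   interpretable as the target between-accession F_ST.  Values below
#'   1e-6 are treated as the zero-drift limit (accession frequencies
#'   equal the ancestral ones exactly).
#' @param fis within-accession inbreeding coefficient in \[0, 1\].
#' @param ancestral_freq_range range the ancestral major-allele frequency
#'   is drawn from, uniformly.
#' @param md_target overall missing-data rate for individual scores in
#'   \[0, 1); per-marker rates are Beta-distributed around this mean.
#' @param pool_sizes strictly increasing pool sizes; the largest must not
#'   exceed `n_individuals_per_accession`.
#' @param tissue_replicates duplicate tissue pools per (accession, size).
#' @param library_depth_classes per-library sequencing depths in millions
#'   of reads (Mr).  Depths are interpreted against
#'   `reference_marker_count` markers, so desk-scale runs with few
#'   simulated markers keep the per-marker coverage (and the depth-class
#'   ratio) of a full-size experiment.
#' @param reference_marker_count marker count the depth classes refer to.
#' @param contribution_cv coefficient of variation of the per-individual
#'   DNA contribution to a pool (Gamma weights); 0 means exactly equal
#'   contributions.
#' @param coverage_dispersion negative-binomial size parameter of the
#'   per-marker coverage distribution (smaller = more overdispersed).
#' @param error_rate per-read probability that an allele is miscalled as
#'   the other allele.
#' @param seed optional integer seed stored with the configuration and
#'   used by [simulate_dataset()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 5,
                       n_markers = 2000,
                       n_individuals_per_accession = 60,
                       divergence_theta = 0.15,
                       fis = 0.2,
                       ancestral_freq_range = c(0.88, 0.999),
                       md_target = 0.29,
                       pool_sizes = c(20, 30, 40, 50, 60),
                       tissue_replicates = 2,
                       library_depth_classes = c(0.9, 1.5),
                       reference_marker_count = 130261,
                       contribution_cv = 0.3,
                       coverage_dispersion = 5,
                       error_rate = 0.005,
                       seed = NULL) {
  stopifnot(n_accessions >= 1, n_markers >= 1,
            n_individuals_per_accession >= 1)
  if (!is.numeric(divergence_theta) || divergence_theta <= 0 ||
      divergence_theta >= 1)
    stop("divergence_theta must lie strictly between 0 and 1")
  stopifnot(fis >= 0, fis <= 1,
            length(ancestral_freq_range) == 2,
            all(ancestral_freq_range > 0), all(ancestral_freq_range < 1),
            ancestral_freq_range[1] <= ancestral_freq_range[2],
            md_target >= 0, md_target < 1,
            tissue_replicates >= 1,
            all(library_depth_classes > 0),
            !anyDuplicated(library_depth_classes),
            reference_marker_count >= 1,
            contribution_cv >= 0, coverage_dispersion > 0,
            error_rate >= 0, error_rate < 0.5)
  if (is.unsorted(pool_sizes, strictly = TRUE))
    stop("pool_sizes must be strictly increasing")
  if (max(pool_sizes) > n_individuals_per_accession)
    stop("largest pool size exceeds the number of individuals per accession")
  structure(list(
    n_accessions = as.integer(n_accessions),
    n_markers = as.integer(n_markers),
    n_individuals_per_accession = as.integer(n_individuals_per_accession),
    divergence_theta = divergence_theta,
    fis = fis,
    ancestral_freq_range = ancestral_freq_range,
    md_target = md_target,
    pool_sizes = as.integer(pool_sizes),
    tissue_replicates = as.integer(tissue_replicates),
    library_depth_classes = library_depth_classes,
    reference_marker_count = reference_marker_count,
    contribution_cv = contribution_cv,
    coverage_dispersion = coverage_dispersion,
    error_rate = error_rate,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

accession_ids <- function(config) {
  sprintf("ACC%02d", seq_len(config$n_accessions))
}

sim_marker_ids <- function(config) {
  sprintf("M%06d", seq_len(config$n_markers))
}

individual_ids <- function(accession, n) {
  sprintf("%s_%03d", accession, seq_len(n))
}

# mean per-marker coverage (reads) for one library of a given depth class
library_mean_coverage <- function(config, depth_class) {
  depth_class * 1e6 / config$reference_marker_count
}

#' Draw ancestral and accession-level allele frequencies
#'
#' The ancestral major-allele frequency of each marker is uniform on
#' `config$ancestral_freq_range`.  Each accession's frequency is then
#' drawn from a Beta distribution with mean equal to the ancestral
#' frequency and variance `theta * p * (1 - p)` (the Balding-Nichols
#' model), so `divergence_theta` plays the role of the between-accession
#' F_ST.  `theta < 1e-6` is treated as the degenerate zero-drift limit.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return A `true_frequencies` object: list with `ancestral_p` (length
#'   `n_markers`) and `accession_p` (markers x accessions matrix).
#' @export
simulate_metapopulation <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  theta <- config$divergence_theta
  p <- stats::runif(config$n_markers,
                    config$ancestral_freq_range[1],
                    config$ancestral_freq_range[2])
  accs <- accession_ids(config)
  if (theta < 1e-6) {
    ap <- matrix(rep(p, length(accs)), ncol = length(accs))
  } else {
    scale <- (1 - theta) / theta
    ap <- vapply(accs, function(a) {
      stats::rbeta(config$n_markers, p * scale, (1 - p) * scale)
    }, numeric(config$n_markers))
  }
  dimnames(ap) <- list(sim_marker_ids(config), accs)
  structure(list(ancestral_p = stats::setNames(p, sim_marker_ids(config)),
                 accession_p = ap),
            class = "true_frequencies")
}

#' Simulate individual genotypes for one accession
#'
#' Genotypes follow inbreeding-adjusted Hardy-Weinberg proportions:
#' P(hom-major) = p^2 + fis*p*q, P(het) = 2pq(1 - fis),
#' P(hom-minor) = q^2 + fis*p*q.  No missing data are introduced here
#' (see [apply_missingness()]).
#'
#' @param truth a `true_frequencies` object.
#' @param accession accession id (column of `truth$accession_p`).
#' @param n number of individuals.
#' @param fis inbreeding coefficient in \[0, 1\].
#' @param seed optional integer seed.
#' @return A [score_matrix()] for the accession's individuals.
#' @export
simulate_genotypes <- function(truth, accession, n, fis, seed = NULL) {
  if (!accession %in% colnames(truth$accession_p))
    stop("unknown accession: ", accession)
  stopifnot(n >= 1, fis >= 0, fis <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- stats::setNames(truth$accession_p[, accession],
                       rownames(truth$accession_p))
  q <- 1 - p
  p_hom <- p^2 + fis * p * q
  p_het <- 2 * p * q * (1 - fis)
  m <- length(p)
  u <- matrix(stats::runif(m * n), nrow = m)
  g <- matrix(0L, nrow = m, ncol = n)
  g[u >= p_hom] <- 1L
  g[u >= p_hom + p_het] <- 2L
  ids <- individual_ids(accession, n)
  dimnames(g) <- list(names(p), ids)
  score_matrix(g, stats::setNames(rep(accession, n), ids))
}

# simulate genotypes for every accession in one score matrix
simulate_scores <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  accs <- colnames(truth$accession_p)
  mats <- lapply(accs, function(a)
    simulate_genotypes(truth, a, config$n_individuals_per_accession,
                       config$fis))
  g <- do.call(cbind, lapply(mats, unclass))
  acc_map <- do.call(c, lapply(mats, sample_accessions))
  score_matrix(g, acc_map)
}

#' Mask individual genotype calls as missing
#'
#' Per-marker missing rates are drawn from a Beta distribution with mean
#' `md_target` and a fixed concentration of 15 (a documented dispersion
#' constant giving realistic marker-to-marker call-rate variation), and
#' entries are masked independently at the marker's rate.  Genotype codes
#' are never recoded, only replaced by `NA`.
#'
#' @param scores a [score_matrix()].
#' @param md_target overall target missing fraction in \[0, 1).
#' @param seed optional integer seed.
#' @return A [score_matrix()] with missing entries.
#' @export
apply_missingness <- function(scores, md_target, seed = NULL) {
  stopifnot(md_target >= 0, md_target < 1)
  if (md_target == 0) return(scores)
  if (!is.null(seed)) set.seed(seed)
  conc <- 15
  m <- nrow(scores)
  rate <- stats::rbeta(m, md_target * conc, (1 - md_target) * conc)
  mask <- matrix(stats::runif(length(scores)) < rate, nrow = m)
  g <- unclass(scores)
  g[mask] <- NA_integer_
  score_matrix(g, sample_accessions(scores))
}

#' Build the nested pool design
#'
#' For each accession a random subset of the smallest pool size is drawn,
#' then extended with further random individuals to form nested supersets
#' at every larger pool size (members of the 20-pool are contained in the
#' 30-pool, and so on).  Each (accession, size) combination yields
#' `tissue_replicates x length(library_depth_classes)` pool-library
#' samples; the two tissue replicates of a combination share membership
#' exactly but receive independent downstream noise.
#'
#' @param config a [sim_config()].
#' @param membership_seed optional integer seed for the membership draw.
#' @return A `pool_design` data frame with columns `pool_sample_id`,
#'   `accession`, `size`, `tissue_rep`, `depth_class` and `member_ids`
#'   (semicolon-joined individual sample ids).
#' @export
build_pool_design <- function(config, membership_seed = NULL) {
  if (!is.null(membership_seed)) set.seed(membership_seed)
  if (max(config$pool_sizes) > config$n_individuals_per_accession)
    stop("pool size exceeds available individuals")
  rows <- list()
  for (a in accession_ids(config)) {
    ids <- individual_ids(a, config$n_individuals_per_accession)
    perm <- sample(ids)  # nested memberships are prefixes of one permutation
    for (s in config$pool_sizes) {
      members <- paste(sort(perm[seq_len(s)]), collapse = ";")
      for (r in seq_len(config$tissue_replicates)) {
        for (d in config$library_depth_classes) {
          rows[[length(rows) + 1L]] <- data.frame(
            pool_sample_id = sprintf("%s_s%02d_r%d_d%g", a, s, r, d),
            accession = a, size = s, tissue_rep = r, depth_class = d,
            member_ids = members, stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(df, class = c("pool_design", "data.frame"))
}

#' Member sample ids of a pool design row set
#' @param design a `pool_design`.
#' @param accession,size the pool to look up.
#' @return character vector of member individual sample ids.
#' @export
pool_members <- function(design, accession, size) {
  rows <- design[design$accession == accession & design$size == size, ]
  if (nrow(rows) == 0)
    stop(sprintf("no pool for accession %s at size %d", accession, size))
  strsplit(rows$member_ids[1], ";", fixed = TRUE)[[1]]
}

#' Simulate pooled allele read counts
#'
#' Tissue, not genotype calls, is pooled: every member contributes its
#' true simulated genotype regardless of missingness in the score data.
#' Per tissue replicate, individual contribution weights are i.i.d. Gamma
#' with coefficient of variation `contribution_cv` (equal weights when
#' 0), normalised to sum to one; the replicate's true major-allele
#' fraction at a marker is the weighted mean of genotype dosages / 2.
#' Both libraries of a replicate share its pooled DNA (hence its weights)
#' but draw coverage independently: per-marker coverage is negative
#' binomial with mean `depth_class * 1e6 / reference_marker_count` and
#' size `coverage_dispersion`, and the major-allele read count is
#' binomial with success probability `f*(1-e) + (1-f)*e` where `e` is the
#' per-read error rate.  Markers drawing coverage 0 yield `(0, 0)` and
#' are treated as missing downstream.
#'
#' @param scores a [score_matrix()] of *complete* (pre-missingness)
#'   genotypes covering all design members.
#' @param design a `pool_design` from [build_pool_design()].
#' @param config the [sim_config()] used to build both.
#' @param seed optional integer seed.
#' @return A [count_matrix()] with one column per pool-library sample.
#' @export
simulate_pool_counts <- function(scores, design, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- unclass(scores)
  if (anyNA(g))
    stop("scores must be the complete pre-missingness matrix")
  m <- nrow(g)
  nA <- na <- matrix(0L, nrow = m, ncol = nrow(design),
                     dimnames = list(rownames(g), design$pool_sample_id))
  # one weight draw per (accession, size, tissue_rep); libraries share it
  rep_key <- paste(design$accession, design$size, design$tissue_rep)
  f_cache <- list()
  for (i in seq_len(nrow(design))) {
    key <- rep_key[i]
    if (is.null(f_cache[[key]])) {
      members <- strsplit(design$member_ids[i], ";", fixed = TRUE)[[1]]
      if (!all(members %in% colnames(g)))
        stop("design membership not covered by score matrix")
      dose <- (2L - g[, members, drop = FALSE]) / 2  # major-allele dosage
      n <- length(members)
      if (config$contribution_cv > 0) {
        shape <- 1 / config$contribution_cv^2
        w <- stats::rgamma(n, shape = shape, rate = shape)
      } else {
        w <- rep(1, n)
      }
      w <- w / sum(w)
      f_cache[[key]] <- as.vector(dose %*% w)
    }
    f <- f_cache[[key]]
    mu <- library_mean_coverage(config, design$depth_class[i])
    cov <- stats::rnbinom(m, size = config$coverage_dispersion, mu = mu)
    e <- config$error_rate
    pr <- f * (1 - e) + (1 - f) * e
    nA[, i] <- stats::rbinom(m, cov, pr)
    na[, i] <- cov - nA[, i]
  }
  count_matrix(nA, na)
}

#' Simulate a complete ind-seq / pool-seq dataset
#'
#' Convenience wrapper running the whole generator: metapopulation
#' frequencies, individual genotypes, missingness masking of the score
#' data, nested pool design, and pooled read counts.  All randomness is
#' governed by one seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list with elements `truth`, `scores_complete` (pre-missing),
#'   `scores` (with missing data), `design` and `counts`.
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  if (is.null(seed)) stop("a seed is required for a reproducible dataset")
  set.seed(seed)
  truth <- simulate_metapopulation(config, seed = NULL)
  scores_complete <- simulate_scores(truth, config)
  scores <- apply_missingness(scores_complete, config$md_target)
  design <- build_pool_design(config)
  counts <- simulate_pool_counts(scores_complete, design, config)
  list(truth = truth, scores_complete = scores_complete,
       scores = scores, design = design, counts = counts)
}
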