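#' Run the complete simulation-to-statistics experiment
#'
#' Executes the whole evaluation pipeline on synthetic data: simulate a
#' nested pooling experiment, sweep Representativity and CCC over the
#' accession x size x MD x depth x MAF grid, compute ind- and pool-side
#' diversity records and their delta-H_E, between-accession structure
#' (pairwise F_ST, Nei distance matrices from both sources with a Mantel
#' comparison, AMOVA for individuals and pool libraries, MDS), and the
#' factorial group-comparison statistics (one-way ANOVAs with Tukey HSD
#' and Levene checks, two-way ANOVA of delta-H_E on size and depth).
#' Factor-level ANOVAs aggregate the sweep by averaging each accession
#' over all non-tested factors, treating accessions as replicates.
#'
#' @param config a [sim_config()].
#' @param seed integer seed governing all randomness.
#' @param out_dir optional directory; when given, every table is written
#'   as CSV together with a JSON run manifest.
#' @param structure_size sample size used for the structure analyses.
#' @param n_permutations permutations for AMOVA (Mantel uses 999).
#' @return A list of result tables (`sweep`, `diversity`, `delta_he`,
#'   `fst`, `nei_ind`, `nei_pool`, `mantel`, `amova_ind`, `amova_pool`,
#'   `mds_ind`, `mds_pool`, `stats`, `manifest`).
#' @export
run_full_experiment <- function(config, seed, out_dir = NULL,
                                structure_size = 50,
                                n_permutations = 999) {
  stage <- "simulate"
  res <- tryCatch({
    dat <- simulate_dataset(config, seed)
    accs <- accession_ids(config)
    depths <- merged_depth_levels(config$library_depth_classes)

    stage <- "sweep"
    sweep_tab <- concordance_sweep(dat$scores, dat$counts, dat$design)

    stage <- "diversity"
    div <- list()
    for (a in accs) for (s in config$pool_sizes) {
      members <- pool_members(dat$design, a, s)
      div[[length(div) + 1]] <- diversity_ind(dat$scores, a, members)
      for (j in depths)
        div[[length(div) + 1]] <-
          diversity_pool(dat$counts, dat$design, a, s, j)
    }
    div <- do.call(rbind, div)
    dhe <- delta_he(div[div$source == "ind", ], div[div$source == "pool", ])

    stage <- "structure"
    if (!structure_size %in% config$pool_sizes)
      stop("structure_size must be one of the configured pool sizes")
    s0 <- structure_size
    members <- lapply(accs, function(a) pool_members(dat$design, a, s0))
    names(members) <- accs
    fst <- fst_matrix(dat$scores)
    # one global MD/MAF filter across all structure individuals, then
    # per-accession frequencies on the retained loci (dartR-style order)
    all_members <- unlist(members, use.names = FALSE)
    g_all <- unclass(dat$scores)[, all_members, drop = FALSE]
    mf_all <- rowMeans(is.na(g_all))
    n_all <- rowSums(!is.na(g_all))
    p_all <- 1 - rowSums(g_all, na.rm = TRUE) / (2 * pmax(n_all, 1))
    ind_loci <- rownames(g_all)[n_all > 0 & mf_all < 0.10 - 1e-9 &
                                  pmin(p_all, 1 - p_all) > 0.05 + 1e-9]
    if (length(ind_loci) < 2)
      stop("too few loci pass the global structure filters")
    ind_tabs <- lapply(accs, function(a) {
      tab <- ind_allele_frequencies(dat$scores, a, members[[a]])
      out <- tab[tab$marker %in% ind_loci, , drop = FALSE]
      for (at in c("accession", "source", "size", "depth"))
        attr(out, at) <- attr(tab, at)
      class(out) <- class(tab)
      out
    })
    names(ind_tabs) <- accs
    pool_tabs <- lapply(accs, function(a) {
      merged <- merge_pool_replicates(dat$counts, dat$design, a, s0,
                                      depths[3])
      mf <- marker_missing_fraction(dat$counts,
                                    attr(merged, "library_ids"))
      apply_filters(pool_allele_frequencies(merged, a, s0, depths[3]),
                    mf, filter_settings(0.10, 0.01))
    })
    names(pool_tabs) <- accs
    nei_ind <- distance_matrix(ind_tabs, "nei")
    nei_pool <- distance_matrix(pool_tabs, "nei")
    mant <- mantel_test(nei_ind, nei_pool, 999)

    # AMOVA: individuals as units on the ind side; pool libraries (size
    # structure_size, all depth classes) as units on the pool side
    units_ind <- genotype_frequency_units(dat$scores, all_members,
                                          ind_loci)
    grp_ind <- rep(accs, vapply(members, length, 0L))
    am_ind <- amova(units_ind, grp_ind, n_permutations)

    lib_rows <- dat$design[dat$design$size == s0, ]
    pool_loci <- Reduce(intersect, lapply(pool_tabs, function(t) t$marker))
    tot <- dat$counts$major + dat$counts$minor
    punit <- (dat$counts$major / ifelse(tot == 0, NA, tot))[
      pool_loci, lib_rows$pool_sample_id, drop = FALSE]
    am_pool <- amova(t(punit), lib_rows$accession, n_permutations)

    stage <- "mds"
    mds_ind <- classical_mds(distance_matrix(units_ind[, ind_loci],
                                             "rogers"), 3)
    big <- sort(config$pool_sizes, decreasing = TRUE)
    big <- big[seq_len(min(3, length(big)))]
    pool_units <- list()
    for (a in accs) for (s in big) {
      merged <- merge_pool_replicates(dat$counts, dat$design, a, s,
                                      depths[3])
      tot_m <- merged$major[, 1] + merged$minor[, 1]
      pool_units[[sprintf("%s_s%02d", a, s)]] <-
        ifelse(tot_m == 0, NA, merged$major[, 1] / tot_m)
    }
    mds_pool <- classical_mds(
      distance_matrix(do.call(rbind, pool_units), "rogers"),
      min(3, length(pool_units) - 1))

    stage <- "stats"
    stats_out <- factorial_stats(sweep_tab, dhe)

    list(sweep = sweep_tab, diversity = div, delta_he = dhe,
         fst = fst, nei_ind = nei_ind, nei_pool = nei_pool,
         mantel = mant, amova_ind = am_ind, amova_pool = am_pool,
         mds_ind = mds_ind, mds_pool = mds_pool, stats = stats_out,
         manifest = list(
           package = "poolconcord",
           version = as.character(utils::packageVersion("poolconcord")),
           r_version = R.version.string,
           seed = seed, structure_size = structure_size,
           n_permutations = n_permutations,
           config = config[setdiff(names(config), "seed")]))
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

# mean of a sweep response per accession within levels of one factor,
# averaging over all non-tested factors (accessions act as replicates)
aggregate_sweep <- function(sweep_tab, factor_name, response) {
  ok <- !is.na(sweep_tab[[response]])
  stats::aggregate(
    stats::setNames(list(sweep_tab[[response]][ok]), response),
    by = list(accession = sweep_tab$accession[ok],
              level = sweep_tab[[factor_name]][ok]),
    FUN = mean)
}

# the paper-style factorial comparisons on the sweep and delta-H_E tables
factorial_stats <- function(sweep_tab, dhe) {
  out <- list()
  for (resp in c("representativity", "ccc")) {
    for (fac in c("size", "md_max", "depth", "pool_maf")) {
      agg <- aggregate_sweep(sweep_tab, fac, resp)
      an <- one_way_anova(agg[[resp]], agg$level)
      tk <- tukey_hsd(agg[[resp]], agg$level)
      lv <- levene_test(agg[[resp]], agg$level)
      out[[paste(resp, fac, sep = "_by_")]] <-
        list(anova = an, tukey = tk, levene = lv, data = agg)
    }
  }
  ok <- !is.na(dhe$delta)
  out$delta_he_two_way <- two_way_anova(dhe$delta[ok],
                                        dhe$size[ok], dhe$depth[ok])
  out
}

# serialise a result bundle as CSV tables plus a JSON manifest
write_experiment <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name)
    utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  w(res$sweep, "sweep")
  w(res$diversity, "diversity")
  w(res$delta_he, "delta_he")
  wm <- function(m, name)
    utils::write.csv(data.frame(label = rownames(m), as.data.frame(m),
                                check.names = FALSE),
                     file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  wm(as.matrix(res$fst), "fst")
  wm(as.matrix(res$nei_ind), "nei_ind")
  wm(as.matrix(res$nei_pool), "nei_pool")
  wm(res$mds_ind$coordinates, "mds_ind")
  wm(res$mds_pool$coordinates, "mds_pool")
  amova_df <- function(a) data.frame(
    component = c("among", "within"), df = a$df[1:2], ss = a$ss,
    sigma2 = a$sigma, percent = a$percent,
    p_value = c(a$p_value, NA))
  w(amova_df(res$amova_ind), "amova_ind")
  w(amova_df(res$amova_pool), "amova_pool")
  w(data.frame(r = res$mantel$r, p_value = res$mantel$p_value,
               n_permutations = res$mantel$n_permutations), "mantel")
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
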