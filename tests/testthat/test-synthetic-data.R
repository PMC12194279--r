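test_that("metapopulation simulation respects the drift model", {
  cfg <- sim_config(n_accessions = 3, n_markers = 500, seed = 4)

  # seed determinism
  t1 <- simulate_metapopulation(cfg)
  t2 <- simulate_metapopulation(cfg)
  expect_identical(t1, t2)

  # degenerate drift: theta -> 0 collapses accessions onto the ancestor
  cfg0 <- sim_config(n_accessions = 3, n_markers = 500,
                     divergence_theta = 1e-8, seed = 4)
  t0 <- simulate_metapopulation(cfg0)
  expect_lt(max(abs(t0$accession_p - t0$ancestral_p)), 1e-6)

  # frequencies live in [0, 1] and dimensions match the config
  expect_true(all(t1$accession_p >= 0 & t1$accession_p <= 1))
  expect_identical(dim(t1$accession_p), c(500L, 3L))

  # invalid theta rejected
  expect_error(sim_config(divergence_theta = 0), "divergence_theta")
  expect_error(sim_config(divergence_theta = 1), "divergence_theta")
})

test_that("genotypes follow inbreeding-adjusted Hardy-Weinberg", {
  truth <- manual_truth(list(A = c(0.5, 1, 0.7, 0.2)))

  # fixed locus (p = 1) is invariant; fis = 1 kills heterozygotes
  g1 <- simulate_genotypes(truth, "A", n = 200, fis = 0, seed = 1)
  expect_true(all(unclass(g1)[2, ] == 0L))
  g2 <- simulate_genotypes(truth, "A", n = 200, fis = 1, seed = 2)
  expect_true(all(unclass(g2) != 1L))

  # het fraction at p = 0.5, fis = 0 is ~0.5 (binomial Monte Carlo)
  big <- manual_truth(list(A = rep(0.5, 1)))
  g3 <- simulate_genotypes(big, "A", n = 5000, fis = 0, seed = 3)
  expect_equal(mean(unclass(g3)[1, ] == 1L), 0.5, tolerance = 0.04)

  # chi-square goodness of fit to p^2+fpq / 2pq(1-f) / q^2+fpq at n = 1e4
  p <- 0.7; fis <- 0.2
  t4 <- manual_truth(list(A = p))
  g4 <- simulate_genotypes(t4, "A", n = 10000, fis = fis, seed = 4)
  obs <- tabulate(unclass(g4)[1, ] + 1L, 3)
  q <- 1 - p
  expected <- c(p^2 + fis * p * q, 2 * p * q * (1 - fis),
                q^2 + fis * p * q)
  chi <- suppressWarnings(stats::chisq.test(obs, p = expected))
  expect_gt(chi$p.value, 0.001)

  expect_error(simulate_genotypes(truth, "Z", 5, 0), "unknown accession")
})

test_that("missingness masking hits its target and never recodes", {
  cfg <- sim_config(n_accessions = 1, n_markers = 2000,
                    n_individuals_per_accession = 60,
                    pool_sizes = c(20, 60), seed = 9)
  truth <- simulate_metapopulation(cfg)
  sc <- simulate_genotypes(truth, "ACC01", 300, fis = 0.2, seed = 10)

  expect_identical(apply_missingness(sc, 0), sc)

  masked <- apply_missingness(sc, 0.29, seed = 11)
  expect_equal(mean(is.na(masked)), 0.29, tolerance = 0.01)

  # masking invariant: surviving entries equal the originals
  keep <- !is.na(unclass(masked))
  expect_identical(unclass(masked)[keep], unclass(sc)[keep])
})

test_that("pool design is nested with replicate semantics", {
  cfg <- sim_config(seed = 5)
  design <- build_pool_design(cfg, membership_seed = 5)

  # paper design: 5 sizes x 2 replicates x 2 depth classes per accession
  expect_equal(nrow(design), 5 * 5 * 2 * 2)
  expect_equal(sum(design$accession == "ACC01"), 20)

  # strict nesting of memberships along the size ladder
  for (a in unique(design$accession)) {
    sizes <- sort(unique(design$size))
    for (i in seq_len(length(sizes) - 1)) {
      m_small <- pool_members(design, a, sizes[i])
      m_big <- pool_members(design, a, sizes[i + 1])
      expect_length(m_small, sizes[i])
      expect_true(all(m_small %in% m_big))
    }
  }

  # tissue replicates of one (accession, size) share membership exactly
  sub <- design[design$accession == "ACC02" & design$size == 30, ]
  expect_equal(length(unique(sub$member_ids)), 1L)

  expect_error(build_pool_design(
    sim_config(n_individuals_per_accession = 30, pool_sizes = c(20, 40))),
    "pool size")
})

test_that("pooled counts are consistent with the pooled subset truth", {
  cfg <- sim_config(n_accessions = 1, n_markers = 2000,
                    pool_sizes = c(20, 50), contribution_cv = 0,
                    error_rate = 0, md_target = 0,
                    library_depth_classes = c(40000, 60000), seed = 31)
  dat <- simulate_dataset(cfg)
  members <- pool_members(dat$design, "ACC01", 50)
  dose <- (2 - unclass(dat$scores_complete)[, members]) / 2
  f_true <- rowMeans(dose)

  merged <- merge_pool_replicates(dat$counts, dat$design, "ACC01", 50,
                                  2 * (40000 + 60000))
  p_hat <- merged$major[, 1] / (merged$major[, 1] + merged$minor[, 1])

  # consistency at large coverage and mean unbiasedness over 2000 markers
  expect_lt(max(abs(p_hat - f_true)), 0.005)
  expect_lt(abs(mean(p_hat - f_true)), 0.002)

  # total coverage matches the configured library reads within 5%
  lib <- dat$design$pool_sample_id[1]
  lib_reads <- dat$design$depth_class[1] * 1e6 *
    cfg$n_markers / cfg$reference_marker_count
  expect_equal(sum(dat$counts$major[, lib] + dat$counts$minor[, lib]),
               lib_reads, tolerance = 0.05)

  # seed determinism of the full dataset
  expect_identical(simulate_dataset(cfg), dat)
})

test_that("zero-coverage markers become missing and cv inflates variance", {
  # low depth so that some markers draw coverage 0
  cfg <- sim_config(n_accessions = 1, n_markers = 500,
                    pool_sizes = c(20, 30),
                    library_depth_classes = c(0.05, 0.08),
                    coverage_dispersion = 1, seed = 13)
  dat <- simulate_dataset(cfg)
  tot <- dat$counts$major + dat$counts$minor
  expect_true(any(tot == 0))
  lib <- colnames(tot)[1]
  mf <- marker_missing_fraction(dat$counts, lib)
  expect_equal(unname(mf[tot[, lib] == 0][1]), 1)

  # variance of pooled p-hat around the subset truth grows with cv
  spread <- sapply(c(0, 0.3, 0.6), function(cv) {
    cfg <- sim_config(n_accessions = 1, n_markers = 1500,
                      pool_sizes = c(20, 30), contribution_cv = cv,
                      error_rate = 0, md_target = 0,
                      library_depth_classes = c(500, 500.1), seed = 77)
    dat <- simulate_dataset(cfg)
    members <- pool_members(dat$design, "ACC01", 30)
    f_true <- rowMeans((2 - unclass(dat$scores_complete)[, members]) / 2)
    lib <- dat$design$pool_sample_id[1]
    p_hat <- dat$counts$major[, lib] /
      (dat$counts$major[, lib] + dat$counts$minor[, lib])
    mean((p_hat - f_true)^2)
  })
  expect_true(all(diff(spread) > 0))
})
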