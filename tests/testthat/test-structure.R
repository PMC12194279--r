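freq_tab <- function(p, markers = paste0("m", seq_along(p))) {
  structure(data.frame(marker = markers, p = p, q = 1 - p, n_used = 10),
            accession = "X", class = c("freq_table", "data.frame"))
}

test_that("Nei and Rogers distances match hand evaluations", {
  a <- freq_tab(c(0.9, 0.3, 0.5))
  expect_equal(nei_distance(a, a), 0)

  # single locus p_a=0.9, p_b=0.6: frozen hand evaluation of Nei (1972)
  expect_equal(nei_distance(freq_tab(0.9), freq_tab(0.6)),
               -log(0.58 / sqrt(0.82 * 0.52)), tolerance = 1e-12)
  expect_equal(nei_distance(freq_tab(0.9), freq_tab(0.6)), 0.1185,
               tolerance = 1e-3)

  # opposite fixation gives infinite distance, flagged not failed
  expect_identical(nei_distance(freq_tab(1), freq_tab(0)), Inf)
  expect_error(nei_distance(freq_tab(0.5, "a"), freq_tab(0.5, "b")),
               "no shared loci")

  expect_equal(rogers_distance(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(rogers_distance(1, 0), 1)
  expect_equal(rogers_distance(0.9, 0.6), 0.3)

  # matrix construction: symmetry, zero diagonal, label equivariance
  tabs <- list(A = freq_tab(c(0.9, 0.2)), B = freq_tab(c(0.6, 0.4)),
               C = freq_tab(c(0.5, 0.5)))
  d <- distance_matrix(tabs, "nei")
  expect_true(isSymmetric(unclass(d)))
  expect_equal(unname(diag(d)), c(0, 0, 0))
  d_perm <- distance_matrix(tabs[c(2, 3, 1)], "nei")
  expect_equal(unclass(d_perm)[names(tabs), names(tabs)], unclass(d),
               ignore_attr = TRUE)
})

test_that("Weir-Cockerham F_ST matches an independent oracle", {
  # worked instance: 2 pops x 4 individuals, 2 loci, enumerated counts
  g <- rbind(L1 = c(0L, 0L, 1L, 1L, 2L, 1L, 0L, 2L),
             L2 = c(0L, 1L, 0L, 0L, 1L, 1L, 1L, 0L))
  ids <- c(sprintf("P1_%03d", 1:4), sprintf("P2_%03d", 1:4))
  colnames(g) <- ids
  sc <- score_matrix(g, stats::setNames(rep(c("P1", "P2"), each = 4), ids))
  loci <- list(
    rbind(P1 = locus_counts(sc, ids[1:4], "L1"),
          P2 = locus_counts(sc, ids[5:8], "L1")),
    rbind(P1 = locus_counts(sc, ids[1:4], "L2"),
          P2 = locus_counts(sc, ids[5:8], "L2")))
  expect_equal(as.numeric(pairwise_fst(sc, "P1", "P2")),
               oracle_wc_theta(loci), tolerance = 1e-8)

  # fixed opposite alleles, no heterozygotes -> theta = 1
  gf <- rbind(L1 = c(0L, 0L, 0L, 2L, 2L, 2L))
  colnames(gf) <- c(sprintf("A_%03d", 1:3), sprintf("B_%03d", 1:3))
  scf <- score_matrix(gf, stats::setNames(rep(c("A", "B"), each = 3),
                                          colnames(gf)))
  expect_equal(as.numeric(pairwise_fst(scf, "A", "B")), 1)

  # null: two accessions drawn from identical frequencies -> |theta| < 0.02
  set.seed(33)
  p <- runif(2000, 0.1, 0.9)
  truth <- manual_truth(list(A = p, B = p))
  sa <- simulate_genotypes(truth, "A", 50, fis = 0, seed = 34)
  sb <- simulate_genotypes(truth, "B", 50, fis = 0, seed = 35)
  g2 <- cbind(unclass(sa), unclass(sb))
  sc2 <- score_matrix(g2, c(sample_accessions(sa), sample_accessions(sb)))
  expect_lt(abs(as.numeric(pairwise_fst(sc2, "A", "B"))), 0.02)

  # theta estimate increases with simulated divergence
  ests <- sapply(c(0.05, 0.25), function(th) {
    cfg <- sim_config(n_accessions = 4, n_markers = 1500,
                      divergence_theta = th, md_target = 0,
                      pool_sizes = c(20, 40), seed = 36)
    truth <- simulate_metapopulation(cfg)
    as.numeric(wc_fst(poolconcord:::simulate_scores(truth, cfg, seed = 37)))
  })
  expect_lt(ests[1], ests[2])
})

test_that("AMOVA decomposes variance and its permutations are seeded", {
  # groups internally identical, fixed opposite between -> 100% among
  units <- rbind(a1 = c(1, 1, 1), a2 = c(1, 1, 1),
                 b1 = c(0, 0, 0), b2 = c(0, 0, 0))
  res <- amova(units, c("a", "a", "b", "b"), n_permutations = 99, seed = 1)
  expect_equal(unname(res$percent["among"]), 100)
  expect_equal(sum(res$percent), 100)
  expect_equal(unname(res$df), c(1, 2, 3))

  # all units identical -> 0% among, p-value uninformative but defined
  same <- matrix(0.5, 4, 3, dimnames = list(paste0("u", 1:4), NULL))
  res0 <- amova(same, c("a", "a", "b", "b"), n_permutations = 49, seed = 2)
  expect_equal(unname(res0$percent["among"]), 0)

  # seeded reproducibility of the permutation p-value
  set.seed(99)
  units2 <- matrix(runif(60), 10, 6,
                   dimnames = list(paste0("u", 1:10), NULL))
  grp <- rep(c("x", "y"), each = 5)
  p1 <- amova(units2, grp, n_permutations = 199, seed = 7)$p_value
  p2 <- amova(units2, grp, n_permutations = 199, seed = 7)$p_value
  expect_identical(p1, p2)

  expect_error(amova(units2, rep("x", 10), 9), "two groups")
  expect_error(amova(units2, c("x", rep("y", 9)), 9), "at least two units")
})

test_that("classical MDS reproduces geometry from distances", {
  # three collinear points: first axis explains everything
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  m <- classical_mds(d, 1)
  expect_equal(m$explained[1], 1)

  # round trip: Euclidean distances reproduced by the embedding
  set.seed(5)
  x <- matrix(rnorm(24), 8, 3)
  rownames(x) <- paste0("u", 1:8)
  dd <- as.matrix(dist(x))
  m2 <- classical_mds(dd, 3)
  expect_equal(as.matrix(dist(m2$coordinates)), dd, tolerance = 1e-8,
               ignore_attr = TRUE)

  # equilateral triangle: two equal positive eigenvalues
  dt <- matrix(1, 3, 3) - diag(3)
  dimnames(dt) <- list(letters[1:3], letters[1:3])
  m3 <- classical_mds(dt, 2)
  ev <- m3$eigenvalues[m3$eigenvalues > 1e-12]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2])

  expect_error(classical_mds(matrix(0, 3, 3), 2), "all-zero")
})

test_that("Mantel test agrees with vegan and honors its seed", {
  set.seed(8)
  x <- matrix(runif(50), 10, 5)
  d1 <- as.matrix(dist(x))
  expect_equal(mantel_test(d1, d1, 99, seed = 1)$r, 1)

  d2 <- max(d1) - d1
  diag(d2) <- 0
  expect_equal(mantel_test(d1, d2, 99, seed = 1)$r, -1)

  d3 <- as.matrix(dist(matrix(runif(50), 10, 5)))
  dimnames(d3) <- dimnames(d1)
  res <- mantel_test(d1, d3, 999, seed = 3)
  ref <- vegan::mantel(d1, d3, permutations = 999)
  expect_equal(res$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(res$p_value - ref$signif), 0.08)

  d_bad <- d3
  rownames(d_bad)[1] <- "zzz"
  expect_error(mantel_test(d1, d_bad, 9), "labels")
})
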