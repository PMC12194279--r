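test_that("one-way ANOVA matches hand computation and stats::aov", {
  # frozen hand case: SSB = 13.5, SSW = 4, df 1/4 -> F = 13.5
  an <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(an$ss, c(13.5, 4))
  expect_equal(an$f[1], 13.5)
  expect_equal(an$df, c(1, 4))

  # two groups with identical values each -> F = 0, p = 1
  flat <- one_way_anova(c(2, 2, 2, 2), c("a", "a", "b", "b"))
  expect_equal(flat$f[1], 0)
  expect_equal(flat$p[1], 1)

  # oracle equivalence against stats::aov on random datasets
  set.seed(10)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(3:7, k, replace = TRUE)
    y <- rnorm(sum(n), mean = rep(rnorm(k, sd = 2), n))
    g <- factor(rep(seq_len(k), n))
    mine <- one_way_anova(y, g)
    ref <- summary(stats::aov(y ~ g))[[1]]
    expect_equal(mine$ss, ref[["Sum Sq"]], tolerance = 1e-8)
    expect_equal(mine$f[1], ref[["F value"]][1], tolerance = 1e-8)
    expect_equal(mine$p[1], ref[["Pr(>F)"]][1], tolerance = 1e-8)
  }

  expect_error(one_way_anova(1:3, rep("a", 3)), "two groups")
})

test_that("two-way ANOVA decomposes balanced designs correctly", {
  # additive cell means with zero noise -> interaction SS = 0
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(c("b1", "b2"), 4)
  y_add <- 1 * (a == "a2") + 2 * (b == "b2")
  an <- two_way_anova(y_add, a, b)
  expect_equal(an$ss[an$term == "A:B"], 0)
  expect_equal(an$ss[an$term == "within"], 0)

  # collapsing factor B to one level reproduces the one-way result
  set.seed(11)
  y <- rnorm(12, mean = rep(c(0, 1, 3), each = 4))
  g <- rep(c("x", "y", "z"), each = 4)
  one <- one_way_anova(y, g)
  # one-level factor B is degenerate; compare against the one-way fit
  ref <- summary(stats::aov(y ~ factor(g)))[[1]]
  expect_equal(one$f[1], ref[["F value"]][1], tolerance = 1e-10)

  # oracle equivalence on random balanced two-way layouts
  for (i in 1:10) {
    ka <- sample(2:3, 1); kb <- sample(2:3, 1); rep_n <- sample(2:4, 1)
    fa <- factor(rep(seq_len(ka), each = kb * rep_n))
    fb <- factor(rep(rep(seq_len(kb), each = rep_n), ka))
    y <- rnorm(length(fa), mean = as.integer(fa) + 0.5 * as.integer(fb))
    mine <- two_way_anova(y, fa, fb)
    ref <- summary(stats::aov(y ~ fa * fb))[[1]]
    expect_equal(mine$ss, ref[["Sum Sq"]], tolerance = 1e-8)
    expect_equal(mine$f[1:3], ref[["F value"]][1:3], tolerance = 1e-8)
  }

  # empty cells are a named hard error
  expect_error(two_way_anova(1:4, c("a", "a", "a", "b"),
                             c("u", "u", "v", "u")),
               "empty design cell: b x v")
})

test_that("Tukey HSD matches closed forms and stats::TukeyHSD", {
  # two groups: Tukey p equals the pooled two-sided t-test p
  set.seed(12)
  y <- c(rnorm(6), rnorm(6, 1))
  g <- rep(c("a", "b"), each = 6)
  tk <- tukey_hsd(y, g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$comparisons$p_adj, tt$p.value, tolerance = 1e-6)

  # identical groups share one letter; well-separated groups do not
  same <- tukey_hsd(rep(c(1, 2), 6), rep(c("a", "b", "c"), each = 4))
  expect_equal(length(unique(same$letters)), 1L)

  y3 <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1), rnorm(5, 20, 0.1))
  g3 <- rep(c("lo", "mid", "hi"), each = 5)
  sep <- tukey_hsd(y3, g3)
  expect_equal(length(unique(sep$letters)), 3L)
  expect_true(all(nchar(sep$letters) == 1))

  # oracle equivalence with stats::TukeyHSD on random balanced data
  for (i in 1:10) {
    k <- sample(3:5, 1)
    y <- rnorm(k * 6, mean = rep(rnorm(k, sd = 1), each = 6))
    g <- factor(rep(letters[seq_len(k)], each = 6))
    mine <- tukey_hsd(y, g)
    ref <- stats::TukeyHSD(stats::aov(y ~ g))$g
    expect_equal(mine$comparisons$p_adj, unname(ref[, "p adj"]),
                 tolerance = 1e-8)
    expect_equal(mine$comparisons$diff, unname(ref[, "diff"]),
                 tolerance = 1e-8)
  }
})

test_that("Levene/Brown-Forsythe test detects heteroscedasticity", {
  # equal groups up to a mean shift -> statistic exactly 0
  base <- c(1, 2, 3, 5, 9)
  lv <- levene_test(c(base, base + 10), rep(c("a", "b"), each = 5))
  expect_equal(lv$statistic, 0)

  # oracle: identical to a one-way ANOVA on |x - median_g|
  set.seed(13)
  y <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  dev <- abs(y - tapply(y, g, median)[g])
  ref <- summary(stats::aov(dev ~ factor(g)))[[1]]
  mine <- levene_test(y, g)
  expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)

  # power: 10-fold variance ratio, n = 30 per group
  set.seed(14)
  yp <- c(rnorm(30, sd = 1), rnorm(30, sd = sqrt(10)))
  expect_lt(levene_test(yp, rep(c("a", "b"), each = 30))$p_value, 0.01)
})

test_that("the full experiment runs, is deterministic, and writes a bundle", {
  cfg <- sim_config(n_accessions = 3, n_markers = 800,
                    pool_sizes = c(20, 50), seed = 3)
  out <- withr::local_tempdir()
  res <- run_full_experiment(cfg, seed = 3, out_dir = out,
                             structure_size = 50, n_permutations = 49)

  expect_equal(nrow(res$sweep), 3 * 2 * 6 * 3 * 2)
  expect_true(all(c("sweep.csv", "diversity.csv", "delta_he.csv",
                    "fst.csv", "nei_ind.csv", "nei_pool.csv",
                    "amova_ind.csv", "amova_pool.csv", "mantel.csv",
                    "mds_ind.csv", "mds_pool.csv", "manifest.json")
                  %in% list.files(out)))
  expect_equal(sum(res$amova_ind$percent), 100)
  expect_equal(unname(res$amova_ind$df), c(2, 147, 149))

  # same seed, same bundle
  res2 <- run_full_experiment(cfg, seed = 3, structure_size = 50,
                              n_permutations = 49)
  expect_identical(res$sweep, res2$sweep)
  expect_identical(res$delta_he, res2$delta_he)
  expect_identical(res$mantel, res2$mantel)

  # factorial stats are present for every response x factor pair
  expect_true(all(c("representativity_by_size", "ccc_by_depth",
                    "delta_he_two_way") %in% names(res$stats)))
})

test_that("the CLI round-trips simulate -> sweep on files", {
  out <- withr::local_tempdir()
  cfgfile <- file.path(out, "config.txt")
  writeLines(c("n_accessions = 2", "n_markers = 120",
               "pool_sizes = 20,40"), cfgfile)
  suppressMessages(poolconcord_cli(c("simulate", "--config", cfgfile,
                                     "--seed", "5", "--out", out)))
  expect_true(file.exists(file.path(out, "score_report.csv")))
  sweep_csv <- file.path(out, "sweep.csv")
  suppressMessages(poolconcord_cli(c(
    "sweep", "--scores", file.path(out, "score_report.csv"),
    "--counts", file.path(out, "count_report.csv"),
    "--design", file.path(out, "pool_design.csv"),
    "--out", sweep_csv)))
  sw <- utils::read.csv(sweep_csv)
  expect_equal(nrow(sw), 2 * 2 * 6 * 3 * 2)
})
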