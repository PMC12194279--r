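#' One-way analysis of variance
#'
#' Standard between/within decomposition with F computed against the F
#' distribution.  Implemented from the textbook sums-of-squares formulas
#' (and cross-checked against `stats::aov` in the test suite).
#'
#' @param values numeric response vector.
#' @param groups factor (or vector) of group labels.
#' @return An `anova_table` data frame with columns `term`, `df`, `ss`,
#'   `ms`, `f`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) stop("need at least two groups")
  if (n - k < 1) stop("no residual degrees of freedom")
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  sizes <- tapply(values, groups, length)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- k - 1; dfw <- n - k
  msb <- ssb / dfb; msw <- ssw / dfw
  f <- if (msw == 0 && msb == 0) 0 else msb / msw
  p <- if (msw == 0 && msb == 0) 1 else stats::pf(f, dfb, dfw,
                                                  lower.tail = FALSE)
  structure(data.frame(
    term = c("between", "within"),
    df = c(dfb, dfw), ss = c(ssb, ssw), ms = c(msb, msw),
    f = c(f, NA), p = c(p, NA), stringsAsFactors = FALSE),
    model = "one-way", response = deparse(substitute(values)),
    class = c("anova_table", "data.frame"))
}

#' Two-way analysis of variance with interaction
#'
#' Balanced-design decomposition into main effects, interaction and
#' residual; empty factor cells are a hard error naming the cell.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b crossed factors.
#' @return An `anova_table` with terms `A`, `B`, `A:B`, `within`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  fa <- droplevels(as.factor(factor_a))
  fb <- droplevels(as.factor(factor_b))
  stopifnot(length(values) == length(fa), length(fa) == length(fb))
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s x %s",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  n <- length(values)
  gm <- mean(values)
  ma <- tapply(values, fa, mean)
  mb <- tapply(values, fb, mean)
  mab <- tapply(values, list(fa, fb), mean)
  na <- tapply(values, fa, length)
  nb <- tapply(values, fb, length)
  nab <- cells
  ss_a <- sum(na * (ma - gm)^2)
  ss_b <- sum(nb * (mb - gm)^2)
  ss_cells <- sum(nab * (mab - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((values - mab[cbind(fa, fb)])^2)
  df_a <- nlevels(fa) - 1
  df_b <- nlevels(fb) - 1
  df_ab <- df_a * df_b
  df_e <- n - nlevels(fa) * nlevels(fb)
  if (df_e < 1) stop("no residual degrees of freedom")
  ms <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab, ss_e / df_e)
  f <- ms[1:3] / ms[4]
  p <- stats::pf(f, c(df_a, df_b, df_ab), df_e, lower.tail = FALSE)
  structure(data.frame(
    term = c("A", "B", "A:B", "within"),
    df = c(df_a, df_b, df_ab, df_e),
    ss = c(ss_a, ss_b, ss_ab, ss_e), ms = ms,
    f = c(f, NA), p = c(p, NA), stringsAsFactors = FALSE),
    model = "two-way",
    factors = c(A = deparse(substitute(factor_a)),
                B = deparse(substitute(factor_b))),
    class = c("anova_table", "data.frame"))
}

# compact letter display by insert-and-absorb over a significance matrix
compact_letters <- function(sig, labels) {
  n <- length(labels)
  cols <- list(rep(TRUE, n))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1]] <- c2
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] | !cols[[cj]]) && !identical(cols[[ci]],
                                                      cols[[cj]]))
        keep[cj] <- FALSE
    }
    # drop exact duplicates
    sig_cols <- vapply(cols, paste, "", collapse = "")
    keep <- keep & !duplicated(sig_cols)
    cols <- cols[keep]
  }
  letters_out <- vapply(seq_len(n), function(i) {
    paste(letters[which(vapply(cols, `[`, TRUE, i))], collapse = "")
  }, "")
  stats::setNames(letters_out, labels)
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise group contrasts after a one-way ANOVA: adjusted p-values
#' from the studentized range distribution with `(k, df_within)`
#' (Tukey-Kramer standard errors for unequal group sizes), confidence
#' intervals, and a compact letter display (groups sharing a letter do
#' not differ at `alpha`).
#'
#' @param values numeric response vector.
#' @param groups factor of group labels.
#' @param alpha significance level for intervals and letters.
#' @return List with `comparisons` (data frame) and `letters` (named
#'   character vector).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  an <- one_way_anova(values, groups)
  k <- nlevels(groups)
  dfw <- an$df[an$term == "within"]
  if (dfw == 0) stop("no residual degrees of freedom")
  mse <- an$ms[an$term == "within"]
  means <- tapply(values, groups, mean)
  sizes <- tapply(values, groups, length)
  levs <- levels(groups)
  pr <- t(utils::combn(k, 2))
  diff <- means[pr[, 2]] - means[pr[, 1]]
  se <- sqrt(mse / 2 * (1 / sizes[pr[, 1]] + 1 / sizes[pr[, 2]]))
  q <- abs(diff) / se
  p <- stats::ptukey(q, k, dfw, lower.tail = FALSE)
  crit <- stats::qtukey(1 - alpha, k, dfw)
  comp <- data.frame(
    group1 = levs[pr[, 1]], group2 = levs[pr[, 2]],
    diff = as.numeric(diff),
    lwr = as.numeric(diff - crit * se), upr = as.numeric(diff + crit * se),
    p_adj = as.numeric(p), stringsAsFactors = FALSE)
  sig <- matrix(FALSE, k, k)
  sig[pr] <- p < alpha
  sig <- sig | t(sig)
  list(comparisons = comp, letters = compact_letters(sig, levs))
}

#' Levene / Brown-Forsythe test of homoscedasticity
#'
#' One-way ANOVA on absolute deviations from group centers; the default
#' center is the group median (Brown-Forsythe, the robust variant), with
#' mean-centering available.
#'
#' @param values numeric response vector.
#' @param groups factor of group labels.
#' @param center `"median"` (default) or `"mean"`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
levene_test <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  fun <- if (center == "median") stats::median else mean
  ctr <- tapply(values, groups, fun)
  dev <- abs(values - ctr[groups])
  an <- one_way_anova(dev, groups)
  list(statistic = an$f[1], df = c(an$df[1], an$df[2]), p_value = an$p[1])
}
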