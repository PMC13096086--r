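# Normality screening (Lilliefors, Monte-Carlo null) and one-way
# repeated-measures comparisons with Bonferroni-corrected pairwise tests.

#' Lilliefors test statistic
#'
#' Kolmogorov-Smirnov distance between the empirical CDF and the normal CDF
#' with mean and SD estimated from the sample. Location-scale invariant.
#'
#' @param x numeric sample (n >= 4)
#' @return the statistic D
#' @export
lilliefors_stat <- function(x) {
  n <- length(x)
  assert_that(n >= 4, "Lilliefors test needs n >= 4")
  s <- stats::sd(x)
  if (s == 0) return(1)
  z <- sort((x - mean(x)) / s)
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - p), max(p - (i - 1) / n))
}

#' Monte-Carlo null distribution of the Lilliefors statistic
#'
#' The null depends only on n, so it can be computed once and reused across
#' many tests of the same sample size.
#'
#' @param n sample size
#' @param nrep replicates (default 2000)
#' @param seed integer seed
#' @return numeric vector of null statistics
#' @export
lilliefors_null <- function(n, nrep = 2000, seed = 0L) {
  with_seed(derive_seed(seed, 404L),
            vapply(seq_len(nrep),
                   function(i) lilliefors_stat(stats::rnorm(n)), numeric(1)))
}

#' Lilliefors normality test
#'
#' Composite-null KS test for normality with estimated mean and SD; the
#' p-value comes from a seeded Monte-Carlo null (no lookup-table
#' interpolation), using the standard (1 + exceedances) / (nrep + 1)
#' estimator. Constant input is flagged degenerate with p at the floor.
#'
#' @param values numeric sample (n >= 4)
#' @param nrep Monte-Carlo replicates (>= 2000 recommended)
#' @param seed integer seed for the null
#' @param null_stats optional precomputed [lilliefors_null()] draws (reused
#'   across many tests of the same n)
#' @return list: `statistic`, `p_value`, `degenerate`
#' @export
lilliefors <- function(values, nrep = 2000, seed = 0L, null_stats = NULL) {
  D <- lilliefors_stat(values)
  if (stats::sd(values) == 0)
    return(list(statistic = 1, p_value = .Machine$double.eps,
                degenerate = TRUE))
  if (is.null(null_stats))
    null_stats <- lilliefors_null(length(values), nrep, seed)
  p <- (1 + sum(null_stats >= D)) / (length(null_stats) + 1)
  list(statistic = D, p_value = p, degenerate = FALSE)
}

as_rm_table <- function(table) {
  m <- as.matrix(table)
  assert_that(all(is.finite(m)), "repeated-measures table must be complete")
  assert_that(ncol(m) >= 2 && nrow(m) >= 3,
              "need >= 2 conditions and >= 3 subjects")
  m
}

#' One-way repeated-measures ANOVA
#'
#' Subjects are the blocking factor: `SS_total` is decomposed into condition,
#' subject and error strata, with `df = (k - 1, (k - 1)(n - 1))`. Complete
#' cases only; no sphericity correction by default (Greenhouse-Geisser via
#' `gg_correction = TRUE`).
#'
#' @param table subjects x conditions numeric matrix (complete cases)
#' @param gg_correction apply the Greenhouse-Geisser epsilon to df and p
#' @return list: `F`, `df` (num, den), `p`, and the sums of squares
#' @export
rm_anova <- function(table, gg_correction = FALSE) {
  m <- as_rm_table(table)
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_cond <- n * sum((colMeans(m) - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  Fv <- if (ms_err > 0) ms_cond / ms_err else ifelse(ms_cond > 0, Inf, 0)
  eps <- 1
  if (gg_correction) {
    S <- stats::cov(m)
    d <- mean(diag(S)); mall <- mean(S); rowm <- rowMeans(S)
    num <- (k * (d - mall))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * mall^2)
    eps <- max(1 / (k - 1), min(1, num / den))
  }
  p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  list(F = Fv, df = c(df1, df2), p = p, epsilon = eps,
       ss = c(condition = ss_cond, subject = ss_subj, error = ss_err))
}

#' Bonferroni-corrected pairwise paired t-tests
#'
#' All condition pairs compared with paired t-tests; each raw p is multiplied
#' by the number of pairs in the family (the pairwise comparisons of one
#' metric within one band) and clipped at 1.
#'
#' @param table subjects x conditions matrix (complete cases)
#' @return data.frame: pair, t, p_raw, p_corrected
#' @export
pairwise_bonferroni <- function(table) {
  m <- as_rm_table(table)
  cn <- colnames(m) %||% paste0("C", seq_len(ncol(m)))
  prs <- utils::combn(ncol(m), 2)
  npair <- ncol(prs)
  out <- data.frame(pair = character(npair), t = NA_real_,
                    p_raw = NA_real_, p_corrected = NA_real_)
  for (j in seq_len(npair)) {
    i1 <- prs[1, j]; i2 <- prs[2, j]
    d <- m[, i1] - m[, i2]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else tt <- stats::t.test(d)
    out$pair[j] <- paste(cn[i1], cn[i2], sep = " vs ")
    out$t[j] <- unname(tt$statistic)
    out$p_raw[j] <- tt$p.value
    out$p_corrected[j] <- min(1, tt$p.value * npair)
  }
  out
}
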