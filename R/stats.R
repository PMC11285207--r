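# Rank-based statistical test battery: Wilcoxon-Mann-Whitney, Spearman,
# Friedman (tie-corrected, implemented in-package), Kruskal-Wallis with
# Dunn's Bonferroni-adjusted post hocs, chi-square cohort balance checks,
# and per-sample anti-flagellin burden summaries.

#' Construct a test result record
#'
#' @param method test name.
#' @param statistic test statistic.
#' @param p two-sided p-value in \code{(0, 1]}.
#' @param p_adjusted optional adjusted p.
#' @param adjustment \code{"bonferroni"} or \code{"none"}.
#' @param n per-group sample sizes.
#' @return object of class \code{test_result}.
#' @export
test_result <- function(method, statistic, p, p_adjusted = NULL,
                        adjustment = "none", n = integer(0)) {
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(method = method, statistic = unname(statistic), p = p,
                 p_adjusted = if (!is.null(p_adjusted))
                   min(max(p_adjusted, p), 1),
                 adjustment = adjustment, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g%s\n", x$method, x$statistic,
              x$p, if (!is.null(x$p_adjusted))
                sprintf(" (adjusted %.3g, %s)", x$p_adjusted, x$adjustment)
              else ""))
  invisible(x)
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact p when both groups have at most 10 observations and there are no
#' ties; normal approximation with tie correction otherwise. The statistic is
#' the Mann-Whitney U for the first group.
#'
#' @param x,y numeric vectors.
#' @return a \code{\link{test_result}}.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop_param("both vectors must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 10L && length(y) <= 10L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # zero-variance tie-only comparison
  test_result("Wilcoxon-Mann-Whitney", wt$statistic, p,
              n = c(length(x), length(y)))
}

#' Spearman rank correlation
#'
#' Midrank ties; two-sided p from the t approximation (exact for small
#' tie-free samples via \code{cor.test}).
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return a \code{\link{test_result}} with the statistic rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_param("need equal lengths >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("undefined correlation: constant vector", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  p <- ct$p.value
  if (is.na(p)) p <- 1    # |rho| = 1 boundary
  res <- test_result("Spearman", ct$estimate, p, n = length(x))
  res$statistic <- unname(ct$estimate)
  res
}

#' Friedman test with midrank tie correction
#'
#' Chi-square statistic on within-block ranks; the tie correction divides by
#' 1 - sum(t^3 - t) / (n (k^3 - k)). Fully tied data (every block constant)
#' is defined as statistic 0, p = 1.
#'
#' @param blocks numeric matrix, rows = blocks (queries), columns =
#'   treatments; no missing cells.
#' @return a \code{\link{test_result}}.
#' @export
friedman <- function(blocks) {
  blocks <- as.matrix(blocks)
  if (anyNA(blocks)) stop_param("missing cells are not allowed")
  n <- nrow(blocks); k <- ncol(blocks)
  if (n < 3L || k < 2L) stop_param("need >= 3 blocks and >= 2 treatments")
  r <- t(apply(blocks, 1, rank))
  Rj <- colSums(r)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  tie_term <- sum(apply(blocks, 1, function(row) {
    t <- table(rank(row))
    sum(t^3 - t)
  }))
  C <- 1 - tie_term / (n * (k^3 - k))
  if (C <= 0) return(test_result("Friedman", 0, 1, n = c(n, k)))
  stat <- stat / C
  test_result("Friedman", stat, pchisq(stat, df = k - 1, lower.tail = FALSE),
              n = c(n, k))
}

#' Kruskal-Wallis with Dunn's Bonferroni-adjusted post hoc tests
#'
#' Tie-corrected Kruskal-Wallis H; when the omnibus p is at most
#' \code{alpha}, Dunn z statistics for all pairwise contrasts, Bonferroni-
#' adjusted over the number of pairs (the pairwise table is always returned;
#' a non-significant omnibus is flagged).
#'
#' @param groups named list of numeric vectors (>= 3 groups, each non-empty).
#' @param alpha omnibus gate for flagging post hocs (default 0.05).
#' @return list: \code{omnibus} (a \code{\link{test_result}}), \code{pairwise}
#'   data frame (contrast, z, p, p_adjusted, significant).
#' @export
kruskal_dunn <- function(groups, alpha = 0.05) {
  if (length(groups) < 3L) stop_param("need >= 3 groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop_param("every group must be non-empty")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  kw <- kruskal.test(groups)
  omnibus <- test_result("Kruskal-Wallis", kw$statistic, kw$p.value,
                         n = vapply(groups, length, integer(1)))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  tie <- table(r)
  tie_term <- sum(tie^3 - tie) / (12 * (N - 1))
  pairs <- combn(names(groups), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    z <- if (se > 0) (rbar[pr[1]] - rbar[pr[2]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    data.frame(contrast = paste(pr, collapse = " vs "),
               z = unname(z), p = p, stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- pmin(1, pw$p * nrow(pw))
  pw$significant <- omnibus$p <= alpha & pw$p_adjusted <= alpha
  list(omnibus = omnibus, pairwise = pw)
}

#' Cohort balance check on age and sex
#'
#' Wilcoxon rank-sum on ordinal age bins (case vs control) and a chi-square
#' (no continuity correction) on the sex-by-group contingency table.
#'
#' @param metadata data frame with columns \code{group}, \code{age_bin},
#'   \code{sex}.
#' @param alpha significance level for the balance verdict.
#' @return list: \code{age} and \code{sex} \code{\link{test_result}}s plus
#'   logical \code{balanced}.
#' @export
cohort_balance_check <- function(metadata, alpha = 0.05) {
  need <- c("group", "age_bin", "sex")
  if (!all(need %in% names(metadata)))
    stop_param("metadata needs columns: ", paste(need, collapse = ", "))
  if (length(unique(metadata$group)) < 2L)
    stop_param("need at least two groups")
  age_ord <- as.integer(factor(metadata$age_bin,
                               levels = sort(unique(metadata$age_bin))))
  grp <- metadata$group == unique(metadata$group)[1]
  age_test <- wilcoxon_rank_sum(age_ord[grp], age_ord[!grp])
  tab <- table(metadata$sex, metadata$group)
  if (nrow(tab) < 2L)
    stop("degenerate sex contingency table (single level)", call. = FALSE)
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  sex_test <- test_result("chi-square", cs$statistic, cs$p.value,
                          n = as.integer(colSums(tab)))
  list(age = age_test, sex = sex_test,
       balanced = age_test$p > alpha && sex_test$p > alpha)
}

#' Per-sample anti-flagellin burden
#'
#' Counts seropositive peptides per sample, the flagellin subset, and their
#' ratio (flagellin / all seropositive; 0 when a sample has no seropositive
#' peptide, with a warning since such samples should normally be QC-excluded).
#'
#' @param calls calls table (\code{\link{enrichment_calls}}).
#' @param flagellin_flags named logical vector: peptide id -> is flagellin.
#' @param groups optional named group vector (sample id -> group) carried
#'   into the output.
#' @return data frame of class \code{sample_burden}: sample_id, group,
#'   n_seropositive_total, n_seropositive_flagellin, flagellin_ratio.
#' @export
flagellin_burden <- function(calls, flagellin_flags, groups = NULL) {
  fl <- flagellin_flags[calls$peptide_id]
  if (anyNA(fl)) stop_param("flagellin_flags missing for some peptides")
  tot <- tapply(calls$seropositive, calls$sample_id, sum)
  fla <- tapply(calls$seropositive & fl, calls$sample_id, sum)
  if (any(tot == 0))
    warning(sum(tot == 0),
            " sample(s) with zero seropositive peptides (ratio set to 0)")
  out <- data.frame(sample_id = names(tot),
                    group = if (is.null(groups)) NA_character_
                            else unname(groups[names(tot)]),
                    n_seropositive_total = as.integer(tot),
                    n_seropositive_flagellin = as.integer(fla),
                    flagellin_ratio = ifelse(tot == 0, 0, fla / tot),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("sample_burden", "data.frame")
  out
}
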