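# Nonparametric group comparisons and region-report assembly. The
# comparison strategy is fixed: chi-square for contingency tables,
# Kruskal-Wallis with Bonferroni-corrected pairwise tests for multiple
# groups, Mann-Whitney U for two groups. Normality/homoscedasticity
# screens are advisory only; the nonparametric path is always taken.

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` on an r x c count table with
#' `df = (r - 1)(c - 1)` and an upper-tail chi-square p-value, without
#' continuity correction.
#'
#' @param tab Matrix (or table) of non-negative integer counts with all row
#'   and column sums positive.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    abort("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("all marginals must be > 0")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration of the U null when both samples have at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction (and continuity correction). The reported `u` is the
#' U statistic of `a` relative to `b`, so complete separation `a < b`
#' yields `u = 0` and `a > b` yields `u = length(a) * length(b)`.
#'
#' @param a,b Numeric samples, both nonempty.
#' @return One-row tibble: `u`, `p_value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) abort("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- max(length(a), length(b)) <= 8 && !ties
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                             correct = TRUE))
  tibble::tibble(u = unname(res$statistic), p_value = res$p.value,
                 method = if (exact) "exact" else "normal_approx")
}

# Tie-corrected Kruskal-Wallis H from a value vector and group factor.
kw_h_statistic <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) return(0)  # all observations identical
  h / corr
}

# Exhaustive enumeration of distinct assignments of the observed values to
# groups of the observed sizes; returns the right-tail probability
# P(H >= h_obs) under the permutation null.
kw_exact_p <- function(x, sizes, h_obs) {
  n <- length(x)
  count <- 0L
  total <- 0L
  recurse <- function(remaining, gsizes, acc_groups) {
    if (!length(gsizes)) {
      g <- factor(rep.int(seq_along(acc_groups),
                          lengths(acc_groups)))
      h <- kw_h_statistic(unlist(acc_groups), g)
      total <<- total + 1L
      if (h >= h_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    idx <- utils::combn(length(remaining), gsizes[1], simplify = FALSE)
    # fix the smallest remaining index into the first group at the last
    # level only when all group sizes are equal? (not needed: sizes may
    # differ, enumerate plainly)
    for (ii in idx)
      recurse(remaining[-ii], gsizes[-1],
              c(acc_groups, list(remaining[ii])))
  }
  recurse(x, sizes, list())
  count / total
}

#' Kruskal-Wallis test with Bonferroni-corrected pairwise comparisons
#'
#' Tie-corrected H statistic over two or more groups. The p-value comes
#' from exhaustive enumeration of the permutation null when the number of
#' distinct group assignments is small (at most `max_exact`), and from the
#' chi-square upper tail with `k - 1` degrees of freedom otherwise. After a
#' global test, pairwise comparisons are run for every group pair and their
#' p-values multiplied by the number of pairs (Bonferroni), capped at 1.
#' The pairwise procedure is Mann-Whitney by default, with Dunn's rank
#' z-test available.
#'
#' @param groups List of numeric vectors (optionally named), each nonempty,
#'   total n >= 3.
#' @param posthoc `"mw"` (pairwise Mann-Whitney) or `"dunn"`.
#' @param p_method `"auto"` (exact when feasible), `"exact"` or
#'   `"asymptotic"`.
#' @param max_exact Largest assignment count enumerated under `"auto"`.
#' @return A `kw_test` object; `glance()` gives `h`, `df`, `p_value`,
#'   `method`; `tidy()` gives the pairwise table.
#' @export
kruskal_wallis_bonferroni <- function(groups, posthoc = c("mw", "dunn"),
                                      p_method = c("auto", "exact",
                                                   "asymptotic"),
                                      max_exact = 2e5) {
  posthoc <- match.arg(posthoc)
  p_method <- match.arg(p_method)
  if (!is.list(groups) || length(groups) < 2L)
    abort("`groups` must be a list of >= 2 samples")
  if (any(lengths(groups) < 1L)) abort("each group needs n >= 1")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) abort("total n must be >= 3")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nm
  sizes <- lengths(groups)
  g <- factor(rep.int(seq_along(groups), sizes))
  h <- kw_h_statistic(x, g)
  k <- length(groups)
  n_assign <- prod(choose(cumsum(rev(sizes)), rev(sizes)))
  use_exact <- p_method == "exact" ||
    (p_method == "auto" && n_assign <= max_exact)
  if (length(unique(x)) == 1L) {
    p <- 1; method <- "degenerate"
  } else if (use_exact) {
    p <- kw_exact_p(x, sizes, h); method <- "exact"
  } else {
    p <- pchisq(h, df = k - 1, lower.tail = FALSE); method <- "asymptotic"
  }
  pairs <- utils::combn(k, 2)
  npairs <- ncol(pairs)
  pw <- lapply(seq_len(npairs), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    praw <- if (posthoc == "mw")
      mann_whitney(groups[[i1]], groups[[i2]])$p_value
    else dunn_p(x, g, i1, i2)
    tibble::tibble(group1 = nm[i1], group2 = nm[i2], p_raw = praw,
                   p_adj = min(1, praw * npairs))
  }) |> dplyr::bind_rows()
  structure(list(h = h, df = k - 1L, p_value = p, method = method,
                 posthoc = posthoc, pairwise = pw,
                 group_sizes = setNames(as.integer(sizes), nm)),
            class = "kw_test")
}

# Dunn's pairwise z-test on the joint ranks, tie-corrected.
dunn_p <- function(x, g, i1, i2) {
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tiecorr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  sigma <- sqrt((n * (n + 1) / 12 - tiecorr) * (1 / ns[i1] + 1 / ns[i2]))
  if (sigma == 0) return(1)
  z <- (rbar[i1] - rbar[i2]) / sigma
  unname(2 * pnorm(-abs(z)))
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (%s)\n",
              x$h, x$df, x$p_value, x$method))
  cat(sprintf("pairwise %s, Bonferroni x%d:\n", x$posthoc,
              nrow(x$pairwise)))
  print(x$pairwise)
  invisible(x)
}

#' @export
glance.kw_test <- function(x, ...)
  tibble::tibble(h = x$h, df = x$df, p_value = x$p_value, method = x$method)

#' @export
tidy.kw_test <- function(x, ...) x$pairwise
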