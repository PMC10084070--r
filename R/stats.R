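#' Kruskal-Wallis omnibus test with exact small-sample option
#'
#' Rank-based Kruskal-Wallis H with tie correction (via
#' [stats::kruskal.test()]) and a chi-square reference p-value
#' (df = k - 1). For total n <= `exact_n_max`, an exact permutation p-value is
#' also computed by full enumeration of all assignments of the pooled values
#' to the group sizes.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param exact_n_max largest total n for which the exact enumeration runs
#'   (default 12).
#' @return Tibble with `H`, `df`, `p_chisq` and `p_exact` (`NA` when not
#'   enumerated).
#' @export
kruskal_wallis <- function(groups, exact_n_max = 12) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(H = 0, df = length(groups) - 1L, p_chisq = 1,
                          p_exact = if (length(values) <= exact_n_max) 1 else NA_real_))
  }
  kt <- stats::kruskal.test(values, g)
  H <- unname(kt$statistic)
  p_exact <- NA_real_
  if (length(values) <= exact_n_max) {
    p_exact <- kw_exact_p(values, lengths(groups), H)
  }
  tibble::tibble(H = H, df = unname(kt$parameter), p_chisq = unname(kt$p.value),
                 p_exact = p_exact)
}

# Exact permutation p for the Kruskal-Wallis H by full enumeration of the
# distinct assignments of pooled ranks to group sizes.
kw_exact_p <- function(values, sizes, H_obs) {
  n <- length(values)
  r <- rank(values)
  # tie correction factor
  ties <- table(r)
  tie_c <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h_of <- function(rank_sets) {
    s2 <- sum(vapply(rank_sets, function(ix) sum(r[ix])^2 / length(ix), numeric(1)))
    (12 / (n * (n + 1)) * s2 - 3 * (n + 1)) / tie_c
  }
  count <- 0L; total <- 0L
  idx_all <- seq_len(n)
  combs1 <- utils::combn(idx_all, sizes[1], simplify = FALSE)
  for (a in combs1) {
    rest1 <- setdiff(idx_all, a)
    if (length(sizes) == 2L) {
      total <- total + 1L
      if (h_of(list(a, rest1)) >= H_obs - 1e-9) count <- count + 1L
    } else if (length(sizes) == 3L) {
      combs2 <- utils::combn(rest1, sizes[2], simplify = FALSE)
      for (b in combs2) {
        total <- total + 1L
        if (h_of(list(a, b, setdiff(rest1, b))) >= H_obs - 1e-9) count <- count + 1L
      }
    } else {
      stop("exact enumeration implemented for 2 or 3 groups", call. = FALSE)
    }
  }
  count / total
}

#' Pairwise rank-sum tests with Bonferroni correction
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum tests for every pair of
#' groups, Bonferroni-adjusted for the `m = 3` location comparisons:
#' `p_adj = min(1, 3 * p_raw)`. Comparisons are independent (not paired):
#' contralateral joints are distinct limbs and group sizes differ.
#'
#' @param groups named list of exactly 3 numeric vectors.
#' @return Tibble with one row per pair: `group_a`, `group_b`, `p_raw`,
#'   `p_adj`, `diff` (mean A - mean B).
#' @export
pairwise_bonferroni <- function(groups) {
  stopifnot(is.list(groups), length(groups) == 3)
  nm <- names(groups)
  combos <- utils::combn(3, 2)
  m <- ncol(combos)
  purrr::map_dfr(seq_len(m), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    p <- if (length(unique(c(groups[[a]], groups[[b]]))) == 1L) 1 else {
      # exact null distribution at these group sizes; falls back to the
      # normal approximation (with a suppressed warning) under ties
      suppressWarnings(stats::wilcox.test(groups[[a]], groups[[b]])$p.value)
    }
    tibble::tibble(
      group_a = nm[a], group_b = nm[b],
      p_raw = p, p_adj = min(1, 3 * p),
      diff = mean(groups[[a]]) - mean(groups[[b]])
    )
  })
}

#' Difference of group means in percentage points
#'
#' @param group_a,group_b numeric vectors (partition percentages or ODs).
#' @param digits rounding for the reported value: 0 for partition
#'   (percentage points, the default), 2 for OD units.
#' @return Rounded `mean(group_a) - mean(group_b)`.
#' @export
diff_pp <- function(group_a, group_b, digits = 0) {
  if (!length(group_a) || !length(group_b)) stop("empty group", call. = FALSE)
  round(mean(group_a) - mean(group_b), digits)
}

#' Compare the three VOI locations
#'
#' The study's group comparison for one value column: Kruskal-Wallis across
#' lesion / 3 mm / contralateral, Bonferroni-corrected pairwise rank-sum
#' tests, and pairwise mean differences.
#'
#' @param data tibble with one row per joint and location.
#' @param value column of values (tidy-eval), e.g. `mean_partition_pct`.
#' @param group column of location labels (default `role`).
#' @return Object of class `location_comparison`; see [tidy.location_comparison()]
#'   and [glance.location_comparison()].
#' @export
compare_locations <- function(data, value, group = role) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  groups <- split(dplyr::pull(data, !!value), dplyr::pull(data, !!group))
  groups <- groups[order(match(names(groups),
                               c("lesion", "away_3mm", "contralateral")))]
  omnibus <- kruskal_wallis(groups)
  pairwise <- if (length(groups) == 3) pairwise_bonferroni(groups) else NULL
  structure(
    list(groups = groups, omnibus = omnibus, pairwise = pairwise,
         value_name = rlang::as_label(value)),
    class = "location_comparison"
  )
}

#' @export
print.location_comparison <- function(x, ...) {
  cat(sprintf("<location_comparison> of %s across %d locations\n",
              x$value_name, length(x$groups)))
  cat(sprintf("  Kruskal-Wallis H = %.3f, p = %.4g\n",
              x$omnibus$H, x$omnibus$p_chisq))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Tidy a location comparison
#'
#' @param x a `location_comparison`.
#' @param ... unused.
#' @return Tibble of pairwise comparisons (`group_a`, `group_b`, `diff`,
#'   `p_raw`, `p_adj`).
#' @export
tidy.location_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) return(tibble::tibble())
  x$pairwise[, c("group_a", "group_b", "diff", "p_raw", "p_adj")]
}

#' Glance at a location comparison
#'
#' @param x a `location_comparison`.
#' @param ... unused.
#' @return One-row tibble: `H`, `df`, `p_chisq`, `p_exact`, `n`.
#' @export
glance.location_comparison <- function(x, ...) {
  dplyr::mutate(x$omnibus, n = sum(lengths(x$groups)))
}

#' Retrospective power of the pairwise comparison
#'
#' Monte-Carlo power of the Bonferroni-adjusted two-sided rank-sum test under
#' independent normal sampling at the given group moments: the fraction of
#' replicates with `min(1, 3 * p_raw) < alpha`.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group moments and sizes.
#' @param alpha significance level (default 0.05).
#' @param m Bonferroni multiplier (default 3, the location pairs).
#' @param reps Monte-Carlo replicates (>= 1000; default 2000).
#' @param seed integer seed.
#' @return Estimated power in \[0, 1\].
#' @export
retrospective_power <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                alpha = 0.05, m = 3, reps = 2000, seed = 1) {
  if (sd_a <= 0 || sd_b <= 0) stop("group SDs must be positive", call. = FALSE)
  if (reps < 1000) stop("use at least 1000 replicates", call. = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  hits <- vapply(seq_len(reps), function(i) {
    a <- stats::rnorm(n_a, mean_a, sd_a)
    b <- stats::rnorm(n_b, mean_b, sd_b)
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    min(1, m * p) < alpha
  }, logical(1))
  mean(hits)
}
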