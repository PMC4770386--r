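# Nonparametric comparison suite: group tests, N-terminal residue-group
# analysis, complex-dispersion outlier detection, ubiquitination
# comparison, correlations and simplified 1D category enrichment.

#' Compare two groups with the appropriate rank test
#'
#' Unpaired groups are compared with a one-sided (or two-sided)
#' Mann-Whitney U test; paired samples with a Wilcoxon signed-rank test.
#' Exact p-values are used for small samples without ties, the normal
#' approximation otherwise (the default behaviour of
#' [stats::wilcox.test()]).  Identical paired samples leave no signed
#' ranks; the result is returned flagged as degenerate with an `NA`
#' p-value rather than as an error.
#'
#' @param values_a,values_b Numeric vectors; aligned and equal-length
#'   when `paired`.
#' @param paired Paired-sample test?
#' @param alternative "less", "greater" (direction of A relative to B)
#'   or "two.sided".
#' @param variable Label carried into the result.
#' @param alpha Significance level for the conclusion label.
#' @return One-row tibble: `variable`, `test`, `alternative`, `p_value`,
#'   `n_a`, `n_b`, `conclusion`, `degenerate`.
#' @export
#' @examples
#' compare_groups(c(1, 2), c(3, 4), alternative = "less")  # p = 1/6
compare_groups <- function(values_a, values_b, paired = FALSE,
                           alternative = c("less", "greater", "two.sided"),
                           variable = "custom", alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (paired && length(values_a) != length(values_b)) {
    stop("paired comparison requires equal-length, aligned samples",
         call. = FALSE)
  }
  test_name <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney"
  degenerate <- paired && all(values_a == values_b)
  p <- if (degenerate) {
    NA_real_
  } else {
    suppressWarnings(
      stats::wilcox.test(values_a, values_b, paired = paired,
                         alternative = alternative)$p.value
    )
  }
  conclusion <- if (!is.na(p) && p <= alpha) {
    switch(alternative,
           less = paste(variable, "A < B"),
           greater = paste(variable, "A > B"),
           two.sided = paste(variable, "A != B"))
  } else {
    "not significant"
  }
  tibble::tibble(variable = variable, test = test_name,
                 alternative = alternative, p_value = p,
                 n_a = length(values_a), n_b = length(values_b),
                 conclusion = conclusion, degenerate = degenerate)
}

kw_statistic <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  rj <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rj^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

kw_exact_p <- function(values, groups) {
  # complete enumeration of all distinct assignments of the pooled
  # observations to groups of the observed sizes; feasible for small N
  groups <- as.character(groups)
  sizes <- table(groups)
  n <- length(values)
  n_arr <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (n_arr > 2e6) {
    stop("exact Kruskal-Wallis enumeration infeasible for these group sizes",
         call. = FALSE)
  }
  h_obs <- kw_statistic(values, groups)
  labels <- names(sizes)
  count <- 0L; total <- 0L
  recurse <- function(avail, gi, assignment) {
    if (gi > length(labels)) {
      h <- kw_statistic(values, assignment)
      total <<- total + 1L
      if (h >= h_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    for (idx in utils::combn(avail, sizes[[gi]], simplify = FALSE)) {
      a2 <- assignment
      a2[idx] <- labels[gi]
      recurse(setdiff(avail, idx), gi + 1L, a2)
    }
  }
  recurse(seq_len(n), 1L, character(n))
  count / total
}

#' N-terminal residue-group analysis of turnover
#'
#' Tests the impact of a categorical grouping (typically the identity of
#' the one or two most N-terminal residues combined with iMet-processing
#' status) on turnover with a Kruskal-Wallis rank sum test, followed by
#' two post-hoc procedures: (a) the multiple-comparison test on mean
#' ranks, where a pair of groups deviates when the absolute difference
#' of mean ranks exceeds the critical difference
#' z(1 - alpha/(k(k-1))) * sqrt(N(N+1)/12 * (1/n_i + 1/n_j)), and
#' (b) uncorrected pairwise Wilcoxon rank-sum tests.
#'
#' @param values Turnover times (or any response).
#' @param groups Group labels, same length.
#' @param alpha Significance level for the post-hoc procedures.
#' @param exact Compute the Kruskal-Wallis p-value by complete
#'   enumeration instead of the chi-square approximation (small samples
#'   only).
#' @return List with `H`, `p_value`, `df`, `critical_pairs` (tibble of
#'   deviating pairs under the mean-rank procedure) and
#'   `wilcoxon_pairs` (tibble of pairwise p-values, flag at `alpha`).
#' @export
residue_group_analysis <- function(values, groups, alpha = 0.05,
                                   exact = FALSE) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs >= 2 members", call. = FALSE)
  kt <- stats::kruskal.test(values, factor(groups))
  p <- if (exact) kw_exact_p(values, groups) else kt$p.value
  # post-hoc (a): critical difference of mean ranks
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  n <- length(values)
  k <- length(sizes)
  combs <- utils::combn(names(sizes), 2, simplify = FALSE)
  crit_rows <- lapply(combs, function(pr) {
    ni <- sizes[[pr[1]]]; nj <- sizes[[pr[2]]]
    crit <- stats::qnorm(1 - alpha / (k * (k - 1))) *
      sqrt(n * (n + 1) / 12 * (1 / ni + 1 / nj))
    diff <- abs(mean_ranks[[pr[1]]] - mean_ranks[[pr[2]]])
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   mean_rank_diff = diff, critical_diff = crit,
                   deviating = diff > crit)
  })
  # post-hoc (b): pairwise Wilcoxon, no multiplicity correction
  wil_rows <- lapply(combs, function(pr) {
    pv <- suppressWarnings(
      stats::wilcox.test(values[groups == pr[1]],
                         values[groups == pr[2]])$p.value
    )
    tibble::tibble(group_a = pr[1], group_b = pr[2], p_value = pv,
                   deviating = !is.na(pv) && pv < alpha)
  })
  list(H = unname(kt$statistic), p_value = p,
       df = unname(kt$parameter),
       critical_pairs = dplyr::bind_rows(crit_rows),
       wilcoxon_pairs = dplyr::bind_rows(wil_rows))
}

#' Group label for the residue-group analysis
#'
#' Builds the categorical label from the utmost N-terminal residues:
#' iMet-retaining N-termini are labelled by Met plus the following
#' residue (e.g. "MN"), iMet-processed N-termini by the exposed residue
#' prefixed to mark cleavage (e.g. "A (iMet cleaved)").
#'
#' @param records Annotated proteoform tibble (`peptide`, `imet_status`).
#' @return Character vector of group labels.
#' @export
nterm_residue_group <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    pep <- records$peptide[i]
    if (records$imet_status[i] == "processed") {
      paste0(substr(pep, 1, 1), " (iMet cleaved)")
    } else {
      substr(pep, 1, 2)
    }
  }, character(1))
}

#' Detect turnover outliers within macromolecular complexes
#'
#' For every complex with at least three members carrying a turnover
#' value, computes all pairwise absolute turnover differences.  Each
#' member is then tested with a one-sided Mann-Whitney U test comparing
#' its own differences to every other member against the differences
#' among the remaining members only; members with significantly larger
#' differences (p <= alpha) are flagged as outliers.  A complex is
#' consistent when no member is flagged.
#'
#' @param turnover Named numeric vector: accession -> turnover time (h).
#' @param complexes Tibble with columns `complex_id`, `accession`.
#' @param alpha One-sided significance level (default 0.05).
#' @return Tibble with one row per tested member: `complex_id`,
#'   `accession`, `p_value`, `outlier`, `consistent` (complex-level
#'   label repeated per member).  Complexes with fewer than three
#'   quantified members are skipped with a message.
#' @export
complex_dispersion <- function(turnover, complexes, alpha = 0.05) {
  rows <- lapply(split(complexes, complexes$complex_id), function(cx) {
    accs <- intersect(cx$accession, names(turnover))
    accs <- accs[is.finite(turnover[accs])]
    if (length(accs) < 3) {
      message("skipping complex ", cx$complex_id[1],
              ": fewer than 3 quantified members")
      return(NULL)
    }
    tt <- turnover[accs]
    pvals <- vapply(seq_along(accs), function(i) {
      test_set <- abs(tt[i] - tt[-i])
      others <- tt[-i]
      pairs <- utils::combn(length(others), 2)
      ref_set <- abs(others[pairs[1, ]] - others[pairs[2, ]])
      if (all(test_set == ref_set[1]) && all(ref_set == ref_set[1])) {
        return(1)
      }
      suppressWarnings(
        stats::wilcox.test(test_set, ref_set,
                           alternative = "greater")$p.value
      )
    }, numeric(1))
    flags <- pvals <= alpha
    tibble::tibble(complex_id = cx$complex_id[1], accession = accs,
                   p_value = pvals, outlier = flags,
                   consistent = !any(flags))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(complex_id = character(), accession = character(),
                          p_value = numeric(), outlier = logical(),
                          consistent = logical())
  }
  out
}

#' Compare turnover of ubiquitinated versus non-ubiquitinated N-termini
#'
#' Group A: database-annotated proteoforms carrying at least one
#' detected ubiquitination site.  Group B: database-annotated
#' proteoforms with one or more lysine residues but no ubiquitination
#' evidence.  Compared with a one-sided Mann-Whitney U test on turnover.
#' Optionally labels dbTIS/aTIS pairs where the longer (dbTIS) form
#' holds a ubiquitination site absent from the shorter form, using a
#' 2-hour relevance threshold on the turnover difference.
#'
#' @param records Tibble with `category`, `lysine_count`,
#'   `ubiquitinated` (logical) and `t_turn_h`.
#' @param pairs Optional tibble of dbTIS/aTIS pairs with
#'   `dbTIS_turnover`, `aTIS_turnover` and `db_unique_site` (logical).
#' @param alternative Direction of group A relative to group B
#'   (default "greater": ubiquitinated more stable).
#' @return List with `comparison` (see [compare_groups()]) and
#'   `pair_labels` (tibble with `delta_turnover` = dbTIS - aTIS and a
#'   `label` of "destabilised", "stabilised" or
#'   "irrelevant difference (<2 h)"; `NULL` when no pairs given).
#' @export
ubiquitination_comparison <- function(records, pairs = NULL,
                                      alternative = "greater") {
  db <- records[records$category == "dbTIS" & is.finite(records$t_turn_h), ]
  a <- db$t_turn_h[db$ubiquitinated]
  b <- db$t_turn_h[!db$ubiquitinated & db$lysine_count >= 1]
  if (length(a) == 0 || length(b) == 0) {
    stop("empty comparison group: need ubiquitinated and lysine-bearing ",
         "non-ubiquitinated dbTIS records", call. = FALSE)
  }
  cmp <- compare_groups(a, b, alternative = alternative,
                        variable = "turnover (ubiquitinated vs not)")
  pair_labels <- NULL
  if (!is.null(pairs)) {
    pu <- pairs[isTRUE_vec(pairs$db_unique_site), ]
    delta <- pu$dbTIS_turnover - pu$aTIS_turnover
    label <- ifelse(abs(delta) < 2, "irrelevant difference (<2 h)",
                    ifelse(delta <= -2, "destabilised", "stabilised"))
    pair_labels <- dplyr::mutate(pu, delta_turnover = delta, label = label)
  }
  list(comparison = cmp, pair_labels = pair_labels)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Correlation between two feature vectors
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method "rank" for Spearman rho, "linear" for Pearson r.
#' @return Correlation coefficient.
#' @export
#' @examples
#' correlate(1:4, c(1, 3, 2, 4))   # rho = 0.8
correlate <- function(x, y, method = c("rank", "linear")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (method == "linear" && (stats::sd(x) == 0 || stats::sd(y) == 0)) {
    stop("constant input: Pearson correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = if (method == "rank") "spearman" else "pearson")
}

#' Simplified 1D category enrichment
#'
#' For every category, compares the values of in-category items against
#' all remaining items with a (by default two-sided) Mann-Whitney U
#' test, applies Benjamini-Hochberg FDR correction across categories and
#' labels the preferred direction (larger or smaller values) from the
#' median difference.  Categories with fewer than two members or fewer
#' than two non-members are skipped with a message.
#'
#' @param membership Tibble with columns `item`, `category` (an item may
#'   belong to several categories).
#' @param values Named numeric vector: item -> value.
#' @param two_sided Two-sided test (default) or one-sided "greater".
#' @return Tibble: `category`, `n_in`, `n_out`, `p_value`, `fdr`,
#'   `direction`.
#' @export
enrichment_1d <- function(membership, values, two_sided = TRUE) {
  cats <- unique(membership$category)
  rows <- lapply(cats, function(ct) {
    inside <- unique(membership$item[membership$category == ct])
    v_in <- values[names(values) %in% inside]
    v_out <- values[!(names(values) %in% inside)]
    v_in <- v_in[is.finite(v_in)]; v_out <- v_out[is.finite(v_out)]
    if (length(v_in) < 2 || length(v_out) < 2) {
      message("skipping category ", ct, ": too few members or non-members")
      return(NULL)
    }
    p <- suppressWarnings(
      stats::wilcox.test(v_in, v_out,
                         alternative = if (two_sided) "two.sided"
                                       else "greater")$p.value
    )
    tibble::tibble(category = ct, n_in = length(v_in),
                   n_out = length(v_out), p_value = p,
                   direction = if (stats::median(v_in) >=
                                     stats::median(v_out)) "larger"
                               else "smaller")
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no testable categories", call. = FALSE)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("category", "n_in", "n_out", "p_value", "fdr", "direction")]
}

#' Feature enrichment in the extreme turnover deciles
#'
#' Flags the 10% least stable (shortest turnover) and 10% most stable
#' (longest turnover) records and tests each decile's feature values
#' against the rest of the cohort via [enrichment_1d()].
#'
#' @param turnover Turnover times.
#' @param feature Feature values (abundance, disorder, ...), same
#'   length and order.
#' @return Enrichment tibble with categories "unstable_decile" and
#'   "stable_decile".
#' @export
extreme_decile_analysis <- function(turnover, feature) {
  keep <- is.finite(turnover) & is.finite(feature)
  turnover <- turnover[keep]; feature <- feature[keep]
  n <- length(turnover)
  if (n < 20) stop("need >= 20 records for decile analysis", call. = FALSE)
  items <- paste0("item", seq_len(n))
  names(feature) <- items
  k <- max(2L, floor(n / 10))
  o <- order(turnover)
  membership <- dplyr::bind_rows(
    tibble::tibble(item = items[o[seq_len(k)]], category = "unstable_decile"),
    tibble::tibble(item = items[o[seq(n - k + 1, n)]],
                   category = "stable_decile")
  )
  enrichment_1d(membership, feature, two_sided = TRUE)
}
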