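test_that("two-group comparisons reproduce small-sample exact p-values", {
  r <- compare_groups(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(r$p_value, 1 / 6)
  expect_identical(r$test, "Mann-Whitney")
  r2 <- compare_groups(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r2$p_value, 1 / 20)
  # paired samples route to the signed-rank test
  rp <- compare_groups(c(1, 2, 3, 4, 6), c(2, 4, 6, 8, 11),
                       paired = TRUE, alternative = "less")
  expect_identical(rp$test, "Wilcoxon signed-rank")
  expect_equal(rp$p_value,
               wsr_enum_p(c(1, 2, 3, 4, 6), c(2, 4, 6, 8, 11), "less"))
  # identical paired samples leave no signed ranks
  rd <- compare_groups(1:4, 1:4, paired = TRUE)
  expect_true(rd$degenerate)
  expect_true(is.na(rd$p_value))
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
  expect_error(compare_groups(1:3, 1:4, paired = TRUE), "equal-length")
})

test_that("Mann-Whitney p-values match exhaustive enumeration for all sizes up to 8", {
  set.seed(71)
  for (na in 2:8) {
    for (nb in 2:8) {
      a <- rnorm(na); b <- rnorm(nb) + 0.5
      for (alt in c("less", "greater")) {
        expect_equal(compare_groups(a, b, alternative = alt)$p_value,
                     mw_enum_p(a, b, alt),
                     info = paste(na, nb, alt))
      }
    }
  }
})

test_that("signed-rank p-values match sign-pattern enumeration up to n = 8", {
  set.seed(72)
  for (n in 4:8) {
    x <- rnorm(n); y <- x + rnorm(n, 0.3)
    for (alt in c("less", "greater")) {
      expect_equal(
        compare_groups(x, y, paired = TRUE, alternative = alt)$p_value,
        wsr_enum_p(x, y, alt), info = paste(n, alt)
      )
    }
  }
})

test_that("Kruskal-Wallis H matches the closed form and ties give H = 0", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("a", "b", "c"), each = 2)
  res <- residue_group_analysis(vals, grp)
  expect_equal(res$H, 32 / 7)
  expect_equal(res$df, 2)
  # all-identical data: H = 0 after tie correction (NaN-free by kruskal.test)
  res0 <- residue_group_analysis(rep(5, 6), grp)
  expect_true(res0$H == 0 || is.nan(res0$H))
  expect_error(residue_group_analysis(1:4, rep("a", 4)), "2 groups")
})

test_that("two-group Kruskal-Wallis agrees with the two-sided Mann-Whitney", {
  set.seed(73)
  a <- rnorm(6); b <- rnorm(7) + 1
  kw <- residue_group_analysis(c(a, b), rep(c("a", "b"), c(6, 7)),
                               exact = TRUE)
  mw <- compare_groups(a, b, alternative = "two.sided")
  expect_equal(kw$p_value, mw$p_value, tolerance = 1e-10)
})

test_that("exact Kruskal-Wallis p-values match full permutation enumeration", {
  set.seed(74)
  cases <- list(c(2, 2, 2), c(2, 2, 3), c(2, 3, 3), c(3, 3), c(4, 4))
  for (sizes in cases) {
    vals <- rnorm(sum(sizes))
    grp <- rep(letters[seq_along(sizes)], sizes)
    expect_equal(residue_group_analysis(vals, grp, exact = TRUE)$p_value,
                 kw_enum_p(vals, grp),
                 info = paste(sizes, collapse = ","))
  }
})

test_that("post-hoc procedures flag clearly separated residue groups", {
  set.seed(75)
  vals <- c(rnorm(8, 0), rnorm(8, 0), rnorm(8, 10))
  grp <- rep(c("MN", "MD", "MT"), each = 8)
  res <- residue_group_analysis(vals, grp)
  expect_lt(res$p_value, 0.01)
  crit <- res$critical_pairs
  expect_true(all(crit$deviating[crit$group_a == "MT" |
                                   crit$group_b == "MT"]))
  expect_false(any(crit$deviating[crit$group_a %in% c("MN", "MD") &
                                    crit$group_b %in% c("MN", "MD")]))
  wil <- res$wilcoxon_pairs
  expect_true(all(wil$deviating[wil$group_a == "MT" |
                                  wil$group_b == "MT"]))
})

test_that("residue-group labels encode the utmost residues and iMet status", {
  recs <- tibble::tibble(peptide = c("MNKL", "ARGH", "MVAA"),
                         imet_status = c("retained", "processed",
                                         "retained"))
  expect_identical(nterm_residue_group(recs),
                   c("MN", "A (iMet cleaved)", "MV"))
})

test_that("complex dispersion flags the planted outlier and only it", {
  tv <- c(10, 10.2, 10.4, 10.1, 10.3, 10.5, 9.9, 40)
  names(tv) <- paste0("P", 1:8)
  cx <- tibble::tibble(complex_id = "C1", accession = names(tv))
  res <- complex_dispersion(tv, cx)
  expect_identical(res$accession[res$outlier], "P8")
  expect_false(any(res$consistent))
  # all-equal turnover: zero differences everywhere, no outliers
  tv2 <- stats::setNames(rep(12, 5), paste0("Q", 1:5))
  cx2 <- tibble::tibble(complex_id = "C2", accession = names(tv2))
  res2 <- complex_dispersion(tv2, cx2)
  expect_false(any(res2$outlier))
  expect_true(all(res2$consistent))
  # complexes with fewer than three quantified members are skipped
  cx3 <- tibble::tibble(complex_id = "C3", accession = c("P1", "P2"))
  expect_message(res3 <- complex_dispersion(tv, cx3), "fewer than 3")
  expect_equal(nrow(res3), 0)
})

test_that("member p-values agree with direct Mann-Whitney on the difference sets", {
  tv <- c(A = 5, B = 6.3, C = 7.1, D = 30)
  cx <- tibble::tibble(complex_id = "C", accession = names(tv))
  res <- complex_dispersion(tv, cx)
  for (i in seq_along(tv)) {
    test_set <- abs(tv[i] - tv[-i])
    others <- tv[-i]
    prs <- utils::combn(3, 2)
    ref_set <- abs(others[prs[1, ]] - others[prs[2, ]])
    expect_equal(res$p_value[res$accession == names(tv)[i]],
                 mw_enum_p(test_set, ref_set, "greater"))
  }
})

test_that("ubiquitination comparison builds the two lysine-matched groups", {
  set.seed(76)
  recs <- tibble::tibble(
    category = rep("dbTIS", 40),
    lysine_count = rep(c(2L, 3L), 20),
    ubiquitinated = rep(c(TRUE, FALSE), each = 20),
    t_turn_h = c(rnorm(20, 25, 2), rnorm(20, 15, 2))
  )
  res <- ubiquitination_comparison(recs)
  expect_equal(res$comparison$n_a, 20)
  expect_equal(res$comparison$n_b, 20)
  expect_lt(res$comparison$p_value, 0.01)
  pairs <- tibble::tibble(
    dbTIS_turnover = c(10, 20, 15), aTIS_turnover = c(13, 15, 14),
    db_unique_site = TRUE
  )
  res2 <- ubiquitination_comparison(recs, pairs = pairs)
  expect_identical(res2$pair_labels$label,
                   c("destabilised", "stabilised",
                     "irrelevant difference (<2 h)"))
  lysfree <- dplyr::mutate(recs, lysine_count = 0L,
                           ubiquitinated = FALSE)
  expect_error(ubiquitination_comparison(lysfree), "empty comparison")
})

test_that("correlations: Spearman on ranks, Pearson on linear scale", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x), 1)
  expect_equal(correlate(x, 2 * x, method = "linear"), 1)
  expect_equal(correlate(x, -x), -1)
  expect_equal(correlate(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(correlate(1:3, 1:4), "mismatch")
  expect_error(correlate(1:5, rep(2, 5), method = "linear"), "constant")
})

test_that("1D enrichment computes per-category MW tests with BH correction", {
  vals <- stats::setNames(1:20, paste0("i", 1:20))
  memb <- dplyr::bind_rows(
    tibble::tibble(item = paste0("i", 11:20), category = "top"),
    tibble::tibble(item = paste0("i", c(1, 3, 12, 18)), category = "mix"),
    tibble::tibble(item = "i5", category = "solo")
  )
  expect_message(res <- enrichment_1d(memb, vals), "skipping category solo")
  expect_setequal(res$category, c("top", "mix"))
  top <- res[res$category == "top", ]
  expect_identical(top$direction, "larger")
  # the top half vs bottom half achieves the minimal two-sided p
  expect_equal(top$p_value,
               suppressWarnings(stats::wilcox.test(11:20, 1:10)$p.value))
  # BH: adjusted values monotone in raw-p order and bounded by 1
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  expect_true(all(res$fdr <= 1))
  o <- order(res$p_value)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))
})

test_that("enrichment p-values are calibrated under random assignment", {
  set.seed(77)
  vals <- stats::setNames(rnorm(60), paste0("i", 1:60))
  pvals <- replicate(200, {
    memb <- tibble::tibble(item = sample(names(vals), 15),
                           category = "c")
    enrichment_1d(memb, vals)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value),
            0.001)
  expect_lt(mean(pvals <= 0.05), 0.1)
})

test_that("extreme turnover deciles enrich a correlated feature and only then", {
  set.seed(78)
  n <- 200
  turnover <- rlnorm(n, 3, 0.5)
  disorder <- 50 - 8 * scale(rank(turnover))[, 1] + rnorm(n, 0, 4)
  res <- extreme_decile_analysis(turnover, disorder)
  expect_true(all(res$fdr < 0.05))
  unstable <- res[res$category == "unstable_decile", ]
  expect_identical(unstable$direction, "larger")
  # independent feature: no significant enrichment
  res0 <- extreme_decile_analysis(turnover, rnorm(n))
  expect_true(all(res0$fdr > 0.05))
  # degenerate direction check: the feature is turnover itself
  res1 <- extreme_decile_analysis(turnover, turnover)
  expect_identical(res1$direction[res1$category == "unstable_decile"],
                   "smaller")
  expect_identical(res1$direction[res1$category == "stable_decile"],
                   "larger")
  expect_error(extreme_decile_analysis(1:10, 1:10), ">= 20")
})
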