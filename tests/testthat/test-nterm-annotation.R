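test_that("iMet removal is expected exactly for small-gyration-radius residues", {
  for (aa in c("A", "V", "S", "T", "C", "G", "P")) {
    expect_true(imet_processing_expected(aa))
  }
  for (aa in c("L", "M", "K", "D", "F", "W")) {
    expect_false(imet_processing_expected(aa))
  }
  expect_error(imet_processing_expected("X"), "invalid or ambiguous")
  expect_error(imet_processing_expected("U"), "invalid or ambiguous")
  # the 6-residue variant without Ser is available by configuration
  expect_false(imet_processing_expected("S", cleavable = setdiff(
    IMET_CLEAVABLE, "S"
  )))
})

test_that("peptide starts classify by position and processing rules", {
  prot <- paste0("MVKLDEQRSTAAGHIKLMNPQRSTVWYAGHIKLMNPQRSMSDFGHIKLMN",
                 "PQRSTVWYAAGHIKLMNPQR")  # M at 40, S at 41; M at 1, V at 2
  r1 <- classify_peptide_start("MVKLD", 1, prot)
  expect_identical(r1$category, "dbTIS")
  expect_identical(r1$imet_status, "retained")
  expect_equal(r1$proteoform_length, nchar(prot))

  r2 <- classify_peptide_start("VKLDE", 2, prot)
  expect_identical(r2$category, "dbTIS")
  expect_identical(r2$imet_status, "processed")

  # position-2 start behind a non-cleavable residue 2 is non-compliant
  prot_ml <- paste0("ML", substr(prot, 3, nchar(prot)))
  r2b <- classify_peptide_start("LKLDE", 2, prot_ml)
  expect_identical(r2b$category, "non-compliant")

  # downstream Met-started peptide: aTIS, iMet retained
  r40 <- classify_peptide_start(substr(prot, 40, 49), 40, prot)
  expect_identical(r40$category, "aTIS")
  expect_identical(r40$imet_status, "retained")

  # downstream start behind a Met with cleavable first residue: processed
  r41 <- classify_peptide_start(substr(prot, 41, 50), 41, prot)
  expect_identical(substr(prot, 41, 41), "S")
  expect_identical(r41$category, "aTIS")
  expect_identical(r41$imet_status, "processed")

  # Met-Leu should retain the iMet: Leu start at 41 is non-compliant
  prot_l <- prot
  substr(prot_l, 41, 41) <- "L"
  rl <- classify_peptide_start(substr(prot_l, 41, 50), 41, prot_l)
  expect_identical(rl$category, "non-compliant")

  # internal start with no preceding Met: candidate proteolytic product
  rp <- classify_peptide_start(substr(prot, 10, 19), 10, prot)
  expect_identical(rp$category, "non-compliant")

  expect_error(classify_peptide_start("AAAA", 1, prot), "does not match")
  expect_error(classify_peptide_start("M", 99, prot), "outside sequence")
})

test_that("every peptide gets exactly one category and they partition the input", {
  pr <- generate_proteome(60, atis_fraction = 0.5, seed = 9)
  tab <- tibble::tibble(peptide = pr$truth$peptide,
                        accession = pr$truth$gene,
                        gene = pr$truth$gene, start = pr$truth$start)
  ann <- annotate_peptides(tab, pr$sequences)
  expect_equal(nrow(ann), nrow(tab))
  expect_true(all(ann$category %in% c("dbTIS", "aTIS", "non-compliant")))
})

test_that("classification recovers the generator's truth exactly", {
  pr <- generate_proteome(150, atis_fraction = 0.5, seed = 21)
  tab <- tibble::tibble(peptide = pr$truth$peptide,
                        accession = pr$truth$gene,
                        gene = pr$truth$gene, start = pr$truth$start)
  ann <- annotate_peptides(tab, pr$sequences)
  expect_identical(ann$category, pr$truth$category)
  expect_identical(ann$imet_status, pr$truth$imet_status)
})

test_that("proteoform pairing finds TIS pairs and iMet pairs per gene", {
  recs <- dplyr::bind_rows(
    classify_peptide_start("MVKL", 1, "MVKLAAAMSDFG", "A1", gene = "g1"),
    classify_peptide_start("VKLA", 2, "MVKLAAAMSDFG", "A2", gene = "g1"),
    classify_peptide_start("SDFG", 9, "MVKLAAAMSDFG", "A3", gene = "g1"),
    classify_peptide_start("MKKL", 1, "MKKLAAA", "B1", gene = "g2")
  )
  pp <- pair_proteoforms(recs)
  # both database forms pair with the single aTIS; multiplicity flag off
  expect_equal(nrow(pp$tis_pairs), 2)
  expect_true(all(!pp$tis_pairs$multiple_aTIS))
  expect_setequal(pp$tis_pairs$aTIS_accession, "A3")
  # retained (start 1) + processed (start 2) share the start codon
  expect_equal(nrow(pp$imet_pairs), 1)
  expect_identical(pp$imet_pairs$retained_accession, "A1")
  expect_identical(pp$imet_pairs$processed_accession, "A2")
  # gene with a dbTIS only contributes no pair
  expect_false("B1" %in% pp$tis_pairs$dbTIS_accession)
  # empty input -> empty output
  empty <- pair_proteoforms(recs[0, ])
  expect_equal(nrow(empty$tis_pairs), 0)
  expect_equal(nrow(empty$imet_pairs), 0)
})

test_that("multiple aTIS per gene are all paired and flagged", {
  prot <- "MVKLAAAMSDFGHKLMAPQRST"
  recs <- dplyr::bind_rows(
    classify_peptide_start("MVKL", 1, prot, "A1", gene = "g1"),
    classify_peptide_start("SDFG", 9, prot, "A2", gene = "g1"),
    classify_peptide_start("APQR", 17, prot, "A3", gene = "g1")
  )
  pp <- pair_proteoforms(recs)
  expect_equal(nrow(pp$tis_pairs), 2)
  expect_true(all(pp$tis_pairs$multiple_aTIS))
})

test_that("the mature N-terminus follows the processing rules", {
  prot <- "MVKLAAA"
  ret <- classify_peptide_start("MVKL", 1, prot, "A1")
  pro <- classify_peptide_start("VKLA", 2, prot, "A2")
  expect_identical(select_mature_nterminus(ret, pro)$accession, "A2")
  prot_g <- "MGKLAAA"
  ret_g <- classify_peptide_start("MGKL", 1, prot_g, "B1")
  pro_g <- classify_peptide_start("GKLA", 2, prot_g, "B2")
  expect_identical(select_mature_nterminus(ret_g, pro_g)$accession, "B2")
  # an unpaired record passes through
  ret_l <- classify_peptide_start("MLKL", 1, "MLKLAAA", "C1")
  expect_identical(select_mature_nterminus(ret_l)$accession, "C1")
  expect_error(select_mature_nterminus(ret, ret), "malformed")
})

test_that("origin assignment follows the evidence precedence", {
  prot <- "MVKLAAAMSDFGHKLM"
  atis <- classify_peptide_start("SDFG", 9, prot, "A1", gene = "g")
  ev <- function(...) {
    base <- list(riboseq = FALSE, swissprot_isoform = FALSE,
                 trembl = FALSE, ensembl = FALSE, topfind = FALSE,
                 transcript_support_level = NA, acetylated = FALSE)
    utils::modifyList(base, list(...))
  }
  r <- assign_origin(atis, ev(riboseq = TRUE))
  expect_identical(r$origin, "alternative-initiation")
  expect_true(r$confident)

  r <- assign_origin(atis, ev(ensembl = TRUE, transcript_support_level = 2))
  expect_identical(r$origin, "splicing-likely")
  expect_true(r$confident)

  r <- assign_origin(atis, ev(ensembl = TRUE, transcript_support_level = 5))
  expect_identical(r$origin, "splicing-poor")

  r <- assign_origin(atis, ev(topfind = TRUE))
  expect_identical(r$origin, "proteolysis-candidate")
  expect_false(r$confident)

  # acetylation or Ribo-Seq support disqualifies the proteolysis call
  r <- assign_origin(atis, ev(topfind = TRUE, riboseq = TRUE))
  expect_identical(r$origin, "alternative-initiation")
  expect_true(r$confident)

  # no evidence at all: residual alternative initiation, not confident
  r <- assign_origin(atis, ev())
  expect_identical(r$origin, "alternative-initiation")
  expect_false(r$confident)

  # database starts pass through as annotated
  db <- classify_peptide_start("MVKL", 1, prot, "D1", gene = "g")
  expect_identical(assign_origin(db, ev())$origin, "annotated")

  expect_error(assign_origin(atis, ev(ensembl = TRUE,
                                      transcript_support_level = 0)),
               ">= 1")
})

test_that("adding evidence never demotes a confident record", {
  prot <- "MVKLAAAMSDFGHKLM"
  atis <- classify_peptide_start("SDFG", 9, prot, "A1", gene = "g")
  flags <- c("riboseq", "swissprot_isoform", "trembl", "ensembl",
             "topfind")
  base <- stats::setNames(as.list(rep(FALSE, 5)), flags)
  base$transcript_support_level <- NA
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(combos) <- flags
  for (i in seq_len(nrow(combos))) {
    ev <- utils::modifyList(base, as.list(combos[i, ]))
    before <- assign_origin(atis, ev)
    for (f in flags[!unlist(combos[i, ])]) {
      more <- ev
      more[[f]] <- TRUE
      after <- assign_origin(atis, more)
      expect_false(before$confident && !after$confident)
    }
  }
})
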