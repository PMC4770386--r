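# Classification of N-terminal peptides into proteoform categories.
#
# An N-terminus starting at database position 1 or 2 points to the
# database-annotated translation initiation site (dbTIS); a start beyond
# position 2 that complies with the co-translational processing rules
# (initiator Met retained, or removed ahead of a small-gyration-radius
# residue) points to an alternative initiation site (aTIS).  Everything
# else is a candidate proteolytic product and is excluded from turnover
# analyses.

#' Residues permitting initiator-methionine removal
#'
#' Methionine aminopeptidases remove the initiator Met when the second
#' residue has a small gyration radius: Ala, Val, Ser, Thr, Cys, Gly or
#' Pro.
#' @export
IMET_CLEAVABLE <- c("A", "V", "S", "T", "C", "G", "P")

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

check_residue <- function(residue) {
  if (!is.character(residue) || length(residue) != 1 || nchar(residue) != 1) {
    stop("`second_residue` must be a single amino-acid letter", call. = FALSE)
  }
  if (!(residue %in% AA20)) {
    stop("invalid or ambiguous amino-acid code: ", residue, call. = FALSE)
  }
  residue
}

#' Is initiator-Met removal expected for a given second residue?
#'
#' @param second_residue Single one-letter amino-acid code (the residue
#'   following the initiator Met).
#' @param cleavable Residue set permitting iMet removal; configurable
#'   because the 6-residue variant without Ser is also encountered.
#' @return `TRUE` if the iMet is expected to be removed.
#' @export
#' @examples
#' imet_processing_expected("V")   # TRUE
#' imet_processing_expected("L")   # FALSE
imet_processing_expected <- function(second_residue,
                                     cleavable = IMET_CLEAVABLE) {
  check_residue(second_residue) %in% cleavable
}

#' Classify one N-terminal peptide against its database sequence
#'
#' Applies the positional rules: start 1 keeps the iMet (dbTIS,
#' retained); start 2 is dbTIS with a processed iMet only when residue 2
#' permits removal, otherwise the peptide is non-compliant; a downstream
#' start beginning with Met is an aTIS with retained iMet; a downstream
#' start whose preceding database residue is Met and whose first residue
#' permits removal is an aTIS with processed iMet; all remaining starts
#' are non-compliant (candidate proteolytic products).
#'
#' @param peptide Peptide sequence (upper-case one-letter codes).
#' @param start 1-based start position within `protein_seq`.
#' @param protein_seq Full database protein sequence.
#' @param accession,gene Identifiers carried through.
#' @param acetylated Nt-acetylation evidence flag.
#' @param cleavable iMet-removal residue set.
#' @return A one-row tibble (a `ProteoformRecord`): `accession`, `gene`,
#'   `peptide`, `start`, `category`, `imet_status`, `acetylated`,
#'   `proteoform_length`.
#' @export
classify_peptide_start <- function(peptide, start, protein_seq,
                                   accession = NA_character_,
                                   gene = NA_character_,
                                   acetylated = FALSE,
                                   cleavable = IMET_CLEAVABLE) {
  peptide <- toupper(peptide); protein_seq <- toupper(protein_seq)
  plen <- nchar(protein_seq)
  if (start < 1 || start > plen) {
    stop("start position ", start, " outside sequence of length ", plen,
         call. = FALSE)
  }
  if (substr(protein_seq, start, start + nchar(peptide) - 1) != peptide) {
    stop("peptide does not match protein sequence at position ", start,
         call. = FALSE)
  }
  first <- substr(peptide, 1, 1)
  if (start == 1) {
    category <- "dbTIS"; imet <- "retained"
  } else if (start == 2) {
    if (first %in% cleavable) {
      category <- "dbTIS"; imet <- "processed"
    } else {
      category <- "non-compliant"; imet <- "not-applicable"
    }
  } else if (first == "M") {
    category <- "aTIS"; imet <- "retained"
  } else if (substr(protein_seq, start - 1, start - 1) == "M" &&
             first %in% cleavable) {
    category <- "aTIS"; imet <- "processed"
  } else {
    category <- "non-compliant"; imet <- "not-applicable"
  }
  tibble::tibble(
    accession = accession, gene = gene, peptide = peptide,
    start = as.integer(start), category = category, imet_status = imet,
    acetylated = isTRUE(acetylated),
    proteoform_length = plen - as.integer(start) + 1L
  )
}

#' Annotate a peptide table against a sequence database
#'
#' Vectorised wrapper around [classify_peptide_start()].
#'
#' @param peptides Tibble with columns `peptide`, `accession`, `gene`,
#'   `start` and optionally `acetylation_evidence`.
#' @param sequences Named character vector of protein sequences
#'   (accession -> sequence), e.g. from [read_fasta()].
#' @param cleavable iMet-removal residue set.
#' @return Tibble of `ProteoformRecord` rows.
#' @export
annotate_peptides <- function(peptides, sequences,
                              cleavable = IMET_CLEAVABLE) {
  req <- c("peptide", "accession", "gene", "start")
  miss <- setdiff(req, names(peptides))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  acet <- if ("acetylation_evidence" %in% names(peptides)) {
    as.logical(peptides$acetylation_evidence)
  } else {
    rep(FALSE, nrow(peptides))
  }
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    acc <- peptides$accession[i]
    # proteoform-level accessions resolve through their parent gene
    key <- if (acc %in% names(sequences)) acc else peptides$gene[i]
    if (!key %in% names(sequences)) {
      stop("accession not found in sequence database: ", acc, call. = FALSE)
    }
    classify_peptide_start(peptides$peptide[i], peptides$start[i],
                           sequences[[key]], accession = acc,
                           gene = peptides$gene[i], acetylated = acet[i],
                           cleavable = cleavable)
  })
  dplyr::bind_rows(rows)
}

#' Pair proteoforms within genes
#'
#' Returns (i) every dbTIS x aTIS combination per gene, with a
#' multiplicity flag when a gene carries more than one aTIS, and (ii)
#' iMet-retained/processed record pairs sharing a start codon (starts 1
#' and 2 for the database TIS; starts p and p+1 for a downstream Met at
#' p).
#'
#' @param records Tibble of `ProteoformRecord` rows.
#' @return List with tibbles `tis_pairs` (`gene`, `dbTIS_accession`,
#'   `dbTIS_start`, `aTIS_accession`, `aTIS_start`, `multiple_aTIS`) and
#'   `imet_pairs` (`gene`, `retained_accession`, `processed_accession`,
#'   `met_position`).
#' @export
pair_proteoforms <- function(records) {
  empty_tis <- tibble::tibble(
    gene = character(), dbTIS_accession = character(),
    dbTIS_start = integer(), aTIS_accession = character(),
    aTIS_start = integer(), multiple_aTIS = logical()
  )
  empty_imet <- tibble::tibble(
    gene = character(), retained_accession = character(),
    processed_accession = character(), met_position = integer()
  )
  if (nrow(records) == 0) {
    return(list(tis_pairs = empty_tis, imet_pairs = empty_imet))
  }
  tis <- lapply(split(records, records$gene), function(g) {
    db <- g[g$category == "dbTIS", ]
    at <- g[g$category == "aTIS", ]
    if (nrow(db) == 0 || nrow(at) == 0) return(NULL)
    grid <- expand.grid(i = seq_len(nrow(db)), j = seq_len(nrow(at)))
    tibble::tibble(
      gene = g$gene[1],
      dbTIS_accession = db$accession[grid$i],
      dbTIS_start = db$start[grid$i],
      aTIS_accession = at$accession[grid$j],
      aTIS_start = at$start[grid$j],
      multiple_aTIS = nrow(at) > 1
    )
  })
  # records share a start codon when the retained form starts at the Met
  # and the processed form one residue downstream
  met_pos <- ifelse(records$imet_status == "retained", records$start,
             ifelse(records$imet_status == "processed", records$start - 1L,
                    NA_integer_))
  imet <- lapply(split(seq_len(nrow(records)),
                       paste(records$gene, met_pos)), function(idx) {
    g <- records[idx, ]
    ret <- g[g$imet_status == "retained", ]
    pro <- g[g$imet_status == "processed", ]
    if (nrow(ret) == 0 || nrow(pro) == 0) return(NULL)
    grid <- expand.grid(i = seq_len(nrow(ret)), j = seq_len(nrow(pro)))
    tibble::tibble(
      gene = g$gene[1],
      retained_accession = ret$accession[grid$i],
      processed_accession = pro$accession[grid$j],
      met_position = ret$start[grid$i]
    )
  })
  list(
    tis_pairs = dplyr::bind_rows(c(list(empty_tis), tis)),
    imet_pairs = dplyr::bind_rows(c(list(empty_imet), imet))
  )
}

#' Select the expected mature N-terminus from an iMet pair
#'
#' When both the iMet-retained and iMet-processed form of the same start
#' codon are observed, only the form expected from the processing rules
#' is kept: the processed record when the post-Met residue permits
#' removal, the retained record otherwise.  A single record is returned
#' unchanged.
#'
#' @param retained,processed `ProteoformRecord` rows (one of the two may
#'   be `NULL`).
#' @param cleavable iMet-removal residue set.
#' @return The selected one-row record.
#' @export
select_mature_nterminus <- function(retained, processed = NULL,
                                    cleavable = IMET_CLEAVABLE) {
  if (is.null(processed)) return(retained)
  if (is.null(retained)) return(processed)
  if (retained$imet_status != "retained" ||
      processed$imet_status != "processed" ||
      processed$start != retained$start + 1L) {
    stop("malformed iMet pair: expected retained + processed forms of one start codon",
         call. = FALSE)
  }
  post_met <- substr(retained$peptide, 2, 2)
  if (post_met == "") post_met <- substr(processed$peptide, 1, 1)
  if (post_met %in% cleavable) processed else retained
}

#' Assign the most likely origin of an alternative N-terminus
#'
#' A record is highly confident when at least one metadata source points
#' to translation (Nt-acetylation, Ribo-Seq, Swiss-Prot isoform, TrEMBL
#' or Ensembl).  The origin label is resolved in precedence order:
#' a database match at position 1/2 with transcript support level <= 3
#' is a likely splicing event; direct initiation evidence (Ribo-Seq or
#' Nt-acetylation) otherwise indicates alternative initiation; a
#' database match without transcript support is a poorly supported
#' splicing event; a protease-product knowledgebase match with neither
#' acetylation nor Ribo-Seq support marks a proteolysis candidate; the
#' residue defaults to alternative initiation (e.g. leaky scanning).
#' dbTIS records pass through labelled "annotated".
#'
#' @param record One `ProteoformRecord` row.
#' @param evidence List or one-row tibble with logical fields `riboseq`,
#'   `swissprot_isoform`, `trembl`, `ensembl`, `topfind` and integer
#'   `transcript_support_level` (`NA` when absent).
#' @return List with `origin` and `confident`.
#' @export
assign_origin <- function(record, evidence) {
  ev <- function(field) isTRUE(as.logical(evidence[[field]]))
  tsl <- evidence[["transcript_support_level"]]
  tsl <- if (is.null(tsl) || length(tsl) == 0 || is.na(tsl)) NA_integer_
         else as.integer(tsl)
  if (!is.na(tsl) && tsl < 1) {
    stop("transcript support level must be >= 1", call. = FALSE)
  }
  acet <- isTRUE(record$acetylated) || ev("acetylated")
  confident <- acet || ev("riboseq") || ev("swissprot_isoform") ||
    ev("trembl") || ev("ensembl")
  if (record$category == "dbTIS") {
    return(list(origin = "annotated", confident = TRUE))
  }
  db_match <- ev("swissprot_isoform") || ev("ensembl")
  origin <- if (db_match && !is.na(tsl) && tsl <= 3) {
    "splicing-likely"
  } else if (ev("riboseq") || acet) {
    "alternative-initiation"
  } else if (db_match) {
    "splicing-poor"
  } else if (ev("topfind")) {
    "proteolysis-candidate"
  } else {
    "alternative-initiation"
  }
  list(origin = origin, confident = confident)
}
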