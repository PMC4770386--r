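# Readers and writers for the interchange formats (FASTA, TSV,
# bedGraph) and the end-to-end pipeline driver.  TSV is the table
# format throughout: tab-separated, UTF-8, header row, "Inf" for
# infinite half-lives, empty cell for missing values.

#' Read protein sequences from FASTA
#'
#' The accession is the first whitespace-delimited token of the header.
#' Sequences are upper-cased and validated against the standard
#' 20-letter alphabet; duplicate accessions are rejected.
#'
#' @param path FASTA file.
#' @return Named character vector (accession -> sequence).
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  acc <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(aas))
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "]"), seqs)
  if (any(bad)) {
    stop("invalid residue(s) in sequence(s): ",
         paste(acc[bad], collapse = ", "), call. = FALSE)
  }
  stats::setNames(seqs, acc)
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  aas <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Read an N-terminal peptide quantification table
#'
#' Expects a TSV with columns `peptide`, `accession`, `gene`, `start`,
#' `timepoint_h`, `spectral_count`, `acetylation_evidence` and either
#' the ratio pair (`ratio_ML`, `ratio_HL`) or the intensity triple
#' (`intensity_L`, `intensity_M`, `intensity_H`), from which ratios are
#' computed on read.  Duplicate (accession, timepoint) rows are
#' rejected.
#'
#' @param path TSV file.
#' @return Validated quantification tibble.
#' @export
read_peptide_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("peptide", "accession", "gene", "start", "timepoint_h",
           "spectral_count", "acetylation_evidence")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("peptide table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  has_ratio <- all(c("ratio_ML", "ratio_HL") %in% names(x))
  has_int <- all(c("intensity_L", "intensity_M", "intensity_H") %in%
                   names(x))
  if (!has_ratio && !has_int) {
    stop("peptide table needs ratio_ML/ratio_HL or intensity_L/M/H ",
         "columns", call. = FALSE)
  }
  if (!has_ratio) {
    bad <- which(!is.na(x$intensity_L) & x$intensity_L <= 0)
    if (length(bad)) {
      stop("non-positive light intensity at line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    }
    x$ratio_ML <- x$intensity_M / x$intensity_L
    x$ratio_HL <- x$intensity_H / x$intensity_L
  }
  num <- c("timepoint_h", "ratio_ML", "ratio_HL")
  for (col in num) {
    if (!is.numeric(x[[col]])) {
      stop("non-numeric values in column ", col, call. = FALSE)
    }
  }
  dup <- duplicated(x[, c("accession", "timepoint_h")])
  if (any(dup)) {
    stop("duplicate (accession, timepoint) row(s) at line(s) ",
         paste(which(dup) + 1L, collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a table as TSV
#'
#' Infinite values are serialized as the literal "Inf"; missing values
#' as empty cells.
#'
#' @param x Data frame.
#' @param path Output file.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}

#' Read paired bedGraph coverage tracks plus a transcript annotation
#'
#' bedGraph intervals are 0-based half-open; they are expanded into
#' dense per-nucleotide count vectors of the annotated transcript
#' length.  Overlapping intervals, negative counts and intervals beyond
#' the transcript bounds are rejected; transcripts present in a track
#' but absent from the annotation are an error.  Library totals are
#' taken from optional `chx_total`/`ltm_total` annotation columns, or
#' computed as track sums.
#'
#' @param chx_path,ltm_path bedGraph files for the CHX and LTM
#'   treatments.
#' @param annotation_path TSV with columns `transcript`, `length`,
#'   `cds_start`, `cds_end` (0-based half-open) and optionally
#'   `chx_total`, `ltm_total`, `accession`.
#' @return List of [ribo_track()] objects, named by transcript.
#' @export
read_tracks <- function(chx_path, ltm_path, annotation_path) {
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                         progress = FALSE)
  req <- c("transcript", "length", "cds_start", "cds_end")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann <- dplyr::distinct(ann[, intersect(names(ann),
                                         c(req, "chx_total", "ltm_total"))])
  densify <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (any(S4Vectors::mcols(gr)$score < 0)) {
      stop("negative count in ", path, call. = FALSE)
    }
    out <- list()
    for (tx in unique(as.character(GenomicRanges::seqnames(gr)))) {
      a <- ann[ann$transcript == tx, ]
      if (nrow(a) == 0) {
        stop("transcript missing from annotation: ", tx, call. = FALSE)
      }
      sub <- gr[as.character(GenomicRanges::seqnames(gr)) == tx]
      if (max(GenomicRanges::end(sub)) > a$length[1]) {
        stop("interval out of bounds on transcript ", tx, call. = FALSE)
      }
      red <- GenomicRanges::reduce(sub)
      if (sum(GenomicRanges::width(red)) < sum(GenomicRanges::width(sub))) {
        stop("overlapping intervals on transcript ", tx, call. = FALSE)
      }
      v <- numeric(a$length[1])
      for (j in seq_along(sub)) {
        v[GenomicRanges::start(sub)[j]:GenomicRanges::end(sub)[j]] <-
          S4Vectors::mcols(sub)$score[j]
      }
      out[[tx]] <- v
    }
    out
  }
  chx <- densify(chx_path)
  ltm <- densify(ltm_path)
  tracks <- list()
  for (i in seq_len(nrow(ann))) {
    tx <- ann$transcript[i]
    len <- ann$length[i]
    cv <- if (tx %in% names(chx)) chx[[tx]] else numeric(len)
    lv <- if (tx %in% names(ltm)) ltm[[tx]] else numeric(len)
    tracks[[tx]] <- ribo_track(
      tx, cv, lv, cds_start = ann$cds_start[i], cds_end = ann$cds_end[i],
      chx_total = if ("chx_total" %in% names(ann)) ann$chx_total[i]
                  else NULL,
      ltm_total = if ("ltm_total" %in% names(ann)) ann$ltm_total[i]
                  else NULL
    )
  }
  tracks
}

#' Write ribosome-profiling tracks as paired bedGraph files
#'
#' @param tracks List of [ribo_track()] objects.
#' @param chx_path,ltm_path Output bedGraph files.
#' @export
write_tracks <- function(tracks, chx_path, ltm_path) {
  as_granges <- function(get) {
    runs <- lapply(tracks, function(tr) {
      r <- rle(get(tr))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != 0
      data.frame(tx = rep(tr$transcript, sum(keep)),
                 start = starts[keep], end = ends[keep],
                 score = r$values[keep])
    })
    d <- do.call(rbind, runs)
    GenomicRanges::GRanges(d$tx, IRanges::IRanges(d$start, d$end),
                           score = d$score)
  }
  rtracklayer::export(as_granges(function(tr) tr$chx), chx_path,
                      format = "bedGraph")
  rtracklayer::export(as_granges(function(tr) tr$ltm), ltm_path,
                      format = "bedGraph")
  invisible(c(chx_path, ltm_path))
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated
#' object.
#'
#' @param fasta,peptides Input paths (FASTA sequence database and
#'   peptide quantification TSV).
#' @param chx,ltm,annotation Optional ribosome-profiling inputs (paired
#'   bedGraph files plus transcript annotation TSV).
#' @param out_dir Output directory.
#' @param kinetics A [kinetics_config()].
#' @param thresholds A [tis_thresholds()].
#' @param r_scale Normalization scale for R_LTM-CHX.
#' @param cleavable iMet-removal residue set.
#' @param alpha Significance level for the comparison suite.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, peptides, chx = NULL, ltm = NULL,
                            annotation = NULL, out_dir = ".",
                            kinetics = kinetics_config(),
                            thresholds = tis_thresholds(),
                            r_scale = 1e7, cleavable = IMET_CLEAVABLE,
                            alpha = 0.05, seed = 1L) {
  if (!inherits(kinetics, "kinetics_config")) {
    stop("`kinetics` must be a kinetics_config()", call. = FALSE)
  }
  if (!inherits(thresholds, "tis_thresholds")) {
    stop("`thresholds` must be a tis_thresholds()", call. = FALSE)
  }
  if (r_scale <= 0) stop("`r_scale` must be positive", call. = FALSE)
  if (length(cleavable) == 0 || !all(cleavable %in% AA20)) {
    stop("`cleavable` must be a non-empty subset of the 20 amino acids",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]",
                                    call. = FALSE)
  structure(
    list(fasta = fasta, peptides = peptides, chx = chx, ltm = ltm,
         annotation = annotation, out_dir = out_dir, kinetics = kinetics,
         thresholds = thresholds, r_scale = r_scale,
         cleavable = cleavable, alpha = alpha, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order: annotate N-terminal peptides
#' against the sequence database, fit turnover kinetics with the full
#' filter cascade, compute abundance and hydropathy features, attach
#' Ribo-Seq TIS support when track inputs are configured, and run the
#' aTIS-versus-dbTIS comparison matrix on turnover, spectral counts and
#' NSAF.  Writes `annotated.tsv`, `turnover.tsv`, `tis_calls.tsv` (when
#' applicable), `stats_comparisons.tsv` and a machine-readable
#' `manifest.json` recording the effective configuration and the filter
#' funnel (peptides identified, with enough timepoints, with valid
#' turnover).
#'
#' @param config A [pipeline_config()].
#' @return List with the result tables and the manifest, invisibly
#'   written to `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sequences <- read_fasta(config$fasta)
  quant <- read_peptide_table(config$peptides)

  peptides <- dplyr::distinct(
    quant[, c("peptide", "accession", "gene", "start",
              "acetylation_evidence")]
  )
  annotated <- annotate_peptides(peptides, sequences,
                                 cleavable = config$cleavable)
  turnover <- fit_turnover(quant, config$kinetics)
  annotated <- compute_features(annotated, quant)
  merged <- dplyr::left_join(annotated, turnover, by = "accession")

  tis_calls <- NULL
  if (!is.null(config$chx)) {
    tracks <- read_tracks(config$chx, config$ltm, config$annotation)
    tis_calls <- dplyr::bind_rows(
      lapply(tracks, call_tis, thresholds = config$thresholds,
             scale = config$r_scale)
    )
    ann_tab <- readr::read_tsv(config$annotation, show_col_types = FALSE,
                               progress = FALSE)
    if ("accession" %in% names(ann_tab)) {
      merged <- match_peptides_to_tis(merged, tis_calls, ann_tab)
    }
  }

  compliant <- merged[merged$category != "non-compliant", ]
  a <- compliant[compliant$category == "aTIS", ]
  d <- compliant[compliant$category == "dbTIS", ]
  stats_tab <- NULL
  if (nrow(a) >= 2 && nrow(d) >= 2) {
    cmp_one <- function(var, col, alt) {
      va <- a[[col]][is.finite(a[[col]])]
      vd <- d[[col]][is.finite(d[[col]])]
      if (length(va) < 2 || length(vd) < 2) return(NULL)
      compare_groups(va, vd, alternative = alt, variable = var,
                     alpha = config$alpha)
    }
    stats_tab <- dplyr::bind_rows(
      cmp_one("turnover", "t_turn_h", "greater"),
      cmp_one("spectral counts", "mean_spc", "less"),
      cmp_one("NSAF", "nsaf", "less")
    )
  }

  manifest <- list(
    package = "proturn",
    version = as.character(utils::packageVersion("proturn")),
    seed = config$seed,
    config = list(
      t_cc = config$kinetics$t_cc,
      r2_threshold = config$kinetics$r2_threshold,
      min_timepoints = config$kinetics$min_timepoints,
      r_scale = config$r_scale, alpha = config$alpha,
      cleavable = paste(config$cleavable, collapse = "")
    ),
    funnel = list(
      n_identified = nrow(annotated),
      n_min_timepoints = sum(turnover$n_timepoints >=
                               config$kinetics$min_timepoints),
      n_valid_turnover = sum(turnover$method != "invalid")
    )
  )

  out <- function(name) file.path(config$out_dir, name)
  write_tsv_table(merged, out("annotated.tsv"))
  write_tsv_table(turnover, out("turnover.tsv"))
  if (!is.null(tis_calls)) write_tsv_table(tis_calls, out("tis_calls.tsv"))
  if (!is.null(stats_tab)) {
    write_tsv_table(stats_tab, out("stats_comparisons.tsv"))
  }
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(annotated = merged, turnover = turnover,
                 tis_calls = tis_calls, stats = stats_tab,
                 manifest = manifest))
}
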