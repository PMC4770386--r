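# Translation-initiation-site calling from paired ribosome-profiling
# tracks.  Lactimidomycin (LTM) arrests initiating ribosomes and serves
# as foreground; cycloheximide (CHX) arrests elongating ribosomes and
# serves as background.  All coordinates are transcript-local, 0-based,
# half-open; the annotated start is the first nucleotide of the start
# codon.

#' P-site offset for a ribosome-protected fragment
#'
#' Read-length-dependent shift from the 5' end of an alignment to the
#' ribosomal P-site nucleotide: +12 for reads up to 30 nt, +13 for
#' 31-33 nt, +14 for 34 nt.  Reads outside the retained 26-34 nt range
#' are rejected.
#'
#' @param read_length Read length(s) in nucleotides.
#' @return Offset(s) in nucleotides.
#' @export
#' @examples
#' psite_offset(28)   # 12
#' psite_offset(32)   # 13
psite_offset <- function(read_length) {
  if (any(read_length < 26 | read_length > 34)) {
    stop("read length outside the retained 26-34 nt range", call. = FALSE)
  }
  ifelse(read_length <= 30, 12L, ifelse(read_length <= 33, 13L, 14L))
}

#' TIS-calling score: normalized LTM minus CHX signal
#'
#' R = scale * ltm/ltm_total - scale * chx/chx_total, the difference
#' between the library-normalized foreground and background P-site
#' counts at a position.  The normalization scale defaults to 1e7
#' (signal per ten million mapped P-sites) and is configurable.
#'
#' @param ltm_count,chx_count P-site counts at the position.
#' @param ltm_total,chx_total Total mapped P-sites per library (> 0).
#' @param scale Normalization constant.
#' @return R value(s).
#' @export
r_ltm_chx <- function(ltm_count, chx_count, ltm_total, chx_total,
                      scale = 1e7) {
  if (any(ltm_total <= 0) || any(chx_total <= 0)) {
    stop("library totals must be positive", call. = FALSE)
  }
  if (any(ltm_count < 0) || any(chx_count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  scale * ltm_count / ltm_total - scale * chx_count / chx_total
}

#' Default per-category TIS-calling thresholds
#'
#' Minimum LTM read count and minimum R_LTM-CHX per position category:
#' annotated start 5 / 0.01, CDS-internal 15 / 0.15, 5'UTR / 3'UTR /
#' non-coding 10 / 0.05; plus the half-width of the local-maximum window
#' (7 nt: one codon on either side).
#'
#' @param annotated_count,annotated_r Thresholds at annotated starts.
#' @param cds_count,cds_r Thresholds downstream within the CDS.
#' @param utr_count,utr_r Thresholds in UTRs and non-coding transcripts.
#' @param window Local-maximum window width in nt (odd).
#' @param local_max_all_categories Apply the local-maximum rule beyond
#'   annotated starts (default `TRUE` for consistent peak logic).
#' @return A `tis_thresholds` list.
#' @export
tis_thresholds <- function(annotated_count = 5, annotated_r = 0.01,
                           cds_count = 15, cds_r = 0.15,
                           utr_count = 10, utr_r = 0.05,
                           window = 7, local_max_all_categories = TRUE) {
  stopifnot(window %% 2 == 1, window >= 1)
  structure(
    list(annotated_count = annotated_count, annotated_r = annotated_r,
         cds_count = cds_count, cds_r = cds_r,
         utr_count = utr_count, utr_r = utr_r,
         window = as.integer(window),
         local_max_all_categories = isTRUE(local_max_all_categories)),
    class = "tis_thresholds"
  )
}

#' Construct a ribosome-profiling track pair for one transcript
#'
#' @param transcript Transcript identifier.
#' @param chx,ltm Per-nucleotide P-site count vectors (equal length).
#' @param cds_start,cds_end CDS interval, 0-based half-open; the
#'   annotated start is `cds_start`.  Use `NA` for non-coding
#'   transcripts.
#' @param chx_total,ltm_total Library totals (default: track sums).
#' @return A `ribo_track` list.
#' @export
ribo_track <- function(transcript, chx, ltm, cds_start = NA,
                       cds_end = NA, chx_total = NULL, ltm_total = NULL) {
  if (length(chx) != length(ltm)) {
    stop("CHX and LTM tracks must have equal length", call. = FALSE)
  }
  if (any(chx < 0) || any(ltm < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  len <- length(chx)
  if (!is.na(cds_start)) {
    if (is.na(cds_end) || cds_start < 0 || cds_end > len ||
        cds_start >= cds_end) {
      stop("CDS interval out of track bounds", call. = FALSE)
    }
  }
  structure(
    list(transcript = transcript, length = len, chx = chx, ltm = ltm,
         cds_start = cds_start, cds_end = cds_end,
         chx_total = if (is.null(chx_total)) sum(chx) else chx_total,
         ltm_total = if (is.null(ltm_total)) sum(ltm) else ltm_total),
    class = "ribo_track"
  )
}

position_category <- function(pos, track) {
  if (is.na(track$cds_start)) return("non-coding")
  if (pos == track$cds_start) return("annotated")
  if (pos > track$cds_start && pos < track$cds_end) return("CDS-downstream")
  if (pos < track$cds_start) return("5'UTR")
  "3'UTR"
}

is_local_max <- function(ltm, pos, window) {
  half <- (window - 1L) %/% 2L
  lo <- max(1L, pos + 1L - half); hi <- min(length(ltm), pos + 1L + half)
  win <- ltm[lo:hi]
  peak <- max(win)
  # ties break toward the 5'-most position achieving the window maximum
  ltm[pos + 1L] == peak && (lo - 1L + which.max(win) - 1L) == pos
}

#' Call translation-initiation sites on one transcript
#'
#' Evaluates every position with non-zero LTM signal against the
#' category-specific thresholds: minimum LTM read count, minimum
#' R_LTM-CHX, and (for annotated starts always; for other categories by
#' configuration) the requirement that the position be the local maximum
#' of the LTM signal within a 7-nt window, ties broken toward the
#' 5'-most position.
#'
#' @param track A [ribo_track()].
#' @param thresholds A [tis_thresholds()].
#' @param scale Normalization constant for R (default 1e7).
#' @return Tibble of passing calls: `transcript`, `position` (0-based),
#'   `category`, `ltm_count`, `r_ltm_chx`, `passed`.
#' @export
call_tis <- function(track, thresholds = tis_thresholds(), scale = 1e7) {
  cand <- which(track$ltm > 0) - 1L
  rows <- lapply(cand, function(pos) {
    cat <- position_category(pos, track)
    count <- track$ltm[pos + 1L]
    r <- r_ltm_chx(count, track$chx[pos + 1L], track$ltm_total,
                   track$chx_total, scale)
    min_count <- switch(cat, annotated = thresholds$annotated_count,
                        `CDS-downstream` = thresholds$cds_count,
                        thresholds$utr_count)
    min_r <- switch(cat, annotated = thresholds$annotated_r,
                    `CDS-downstream` = thresholds$cds_r, thresholds$utr_r)
    need_max <- cat == "annotated" || thresholds$local_max_all_categories
    ok <- count >= min_count && r >= min_r &&
      (!need_max || is_local_max(track$ltm, pos, thresholds$window))
    if (!ok) return(NULL)
    tibble::tibble(transcript = track$transcript, position = pos,
                   category = cat, ltm_count = count, r_ltm_chx = r,
                   passed = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(transcript = character(), position = integer(),
                          category = character(), ltm_count = numeric(),
                          r_ltm_chx = numeric(), passed = logical())
  }
  out
}

#' Match N-terminal peptides to called TIS
#'
#' A proteoform gains Ribo-Seq support when a passing TIS call sits at
#' the first nucleotide of the codon encoding its initiator Met.  For
#' iMet-processed records (including position-2 database starts) that
#' codon is the one of the Met immediately preceding the observed start
#' residue.
#'
#' @param records Annotated proteoform tibble (`accession`, `start`,
#'   `imet_status`).
#' @param calls TIS-call tibble from [call_tis()].
#' @param annotation Tibble mapping `accession` to `transcript` and
#'   `cds_start` (0-based first nucleotide of the annotated start
#'   codon).
#' @return `records` with logical column `riboseq_support` and the
#'   matched `tis_position` (`NA` when unsupported) appended.
#' @export
match_peptides_to_tis <- function(records, calls, annotation) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    acc <- records$accession[i]
    ann <- annotation[annotation$accession == acc, ]
    if (nrow(ann) == 0) {
      stop("accession not mappable to a transcript: ", acc, call. = FALSE)
    }
    met_res <- if (records$imet_status[i] == "processed") {
      records$start[i] - 1L
    } else {
      records$start[i]
    }
    nt <- ann$cds_start[1] + 3L * (met_res - 1L)
    hit <- calls[calls$transcript == ann$transcript[1] &
                   calls$position == nt & calls$passed, ]
    tibble::tibble(riboseq_support = nrow(hit) > 0,
                   tis_position = if (nrow(hit) > 0) nt else NA_integer_)
  })
  dplyr::bind_cols(records, dplyr::bind_rows(rows))
}
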