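# Synthetic-data generators with known ground truth.  Every input the
# pipeline consumes (peptide quantification tables, protein sequences,
# ribosome-profiling track pairs, complex membership) can be produced
# here, so all downstream stages are testable without downloads.

#' Measurement noise model for simulated pSILAC data
#'
#' @param sigma Lognormal sigma applied multiplicatively to each channel
#'   intensity (MS intensity noise is approximately multiplicative;
#'   default 0.1).
#' @param missing_prob Probability that a proteoform is not identified
#'   at a given timepoint (default 0.15).
#' @param nonexp_fraction Fraction of proteoforms whose decay follows a
#'   monotone logistic rather than exponential shape, exercising the
#'   linear-interpolation fallback (default 0.01).
#' @param floor Minimum reported intensity (arbitrary units).
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma = 0.1, missing_prob = 0.15,
                        nonexp_fraction = 0.01, floor = 1) {
  stopifnot(sigma >= 0, missing_prob >= 0, missing_prob <= 1,
            nonexp_fraction >= 0, nonexp_fraction <= 1, floor >= 0)
  structure(list(sigma = sigma, missing_prob = missing_prob,
                 nonexp_fraction = nonexp_fraction, floor = floor),
            class = "noise_model")
}

random_protein <- function(len, cleavable_second) {
  second_pool <- if (cleavable_second) IMET_CLEAVABLE
                 else setdiff(AA20, IMET_CLEAVABLE)
  paste0("M", sample(second_pool, 1),
         paste(sample(AA20, len - 2, replace = TRUE), collapse = ""))
}

#' Generate a synthetic proteome with known proteoform structure
#'
#' Produces random protein sequences (length 50-1000) in which a stated
#' fraction of genes carries, besides the database-annotated start, a
#' downstream alternative initiation site at an internal Met whose
#' offset follows a lognormal with median 52 residues.  Second residues
#' are drawn half from the iMet-cleavable set and half from the rest, so
#' both retained and processed database N-termini occur; a configurable
#' fraction of cleavable genes additionally yields both members of a
#' retained/processed iMet pair.  True 50% turnover times are drawn from
#' a lognormal with median 21.6 h (sdlog 1.1), spanning under 1 h to
#' beyond 48 h across a cohort, and converted into the true decay
#' parameter B = ln(1/2)/t_turn and degradation constant
#' k_deg = -B - ln(2)/t_cc (which may be negative for proteoforms more
#' stable than the dividing culture).
#'
#' @param n_genes Number of genes (>= 1).
#' @param atis_fraction Fraction of genes carrying an additional aTIS
#'   proteoform (default 0.2).
#' @param seed Integer seed; identical seeds give identical output.
#' @param t_cc Cell doubling time in hours (default 24).
#' @param tturn_median,tturn_sdlog Lognormal parameters of the true
#'   turnover-time distribution.
#' @param offset_median,offset_sdlog Lognormal parameters of the aTIS
#'   offset distribution (median 52 residues).
#' @param imet_pair_fraction Fraction of cleavable-second-residue genes
#'   for which both the iMet-retained and iMet-processed database
#'   N-terminus are observed (default 0.05).
#' @param atis_abundance_factor Down-weighting of aTIS spectral
#'   abundance relative to dbTIS (default 0.5).
#' @return List with `sequences` (named character vector, one per gene)
#'   and `truth` (tibble with one row per proteoform: `accession`,
#'   `gene`, `category`, `imet_status`, `start`, `met_position`,
#'   `peptide`, `k_deg`, `B`, `t_turn`, `t_cc`, `spc_mean`,
#'   `acetylated`) plus the generator parameters.
#' @export
generate_proteome <- function(n_genes, atis_fraction = 0.2, seed = 1,
                              t_cc = 24, tturn_median = 21.6,
                              tturn_sdlog = 1.1, offset_median = 52,
                              offset_sdlog = 0.7,
                              imet_pair_fraction = 0.05,
                              atis_abundance_factor = 0.5) {
  if (n_genes < 1) stop("`n_genes` must be >= 1", call. = FALSE)
  if (atis_fraction < 0 || atis_fraction > 1) {
    stop("`atis_fraction` must lie in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    lens <- sample(50:1000, n_genes, replace = TRUE)
    cleav2 <- sample(c(TRUE, FALSE), n_genes, replace = TRUE)
    has_atis <- stats::runif(n_genes) < atis_fraction
    seqs <- character(n_genes)
    rows <- list()
    new_form <- function(gene, plen, category, imet, start, met_pos, pep) {
      t_turn <- stats::rlnorm(1, log(tturn_median), tturn_sdlog)
      B <- log(0.5) / t_turn
      spc <- stats::rlnorm(1, log(20), 0.8) *
        (if (category == "aTIS") atis_abundance_factor else 1)
      tibble::tibble(
        accession = paste0(gene, "_", start), gene = gene,
        category = category, imet_status = imet, start = as.integer(start),
        met_position = as.integer(met_pos), peptide = pep,
        k_deg = -B - log(2) / t_cc, B = B, t_turn = t_turn, t_cc = t_cc,
        spc_mean = spc, acetylated = stats::runif(1) < 0.6
      )
    }
    for (i in seq_len(n_genes)) {
      s <- random_protein(lens[i], cleav2[i])
      offset <- NA_integer_
      if (has_atis[i]) {
        offset <- round(stats::rlnorm(1, log(offset_median), offset_sdlog))
        offset <- max(5L, min(as.integer(offset), lens[i] - 20L))
        atis_cleav <- sample(c(TRUE, FALSE), 1)
        after <- if (atis_cleav) sample(IMET_CLEAVABLE, 1)
                 else sample(setdiff(AA20, c(IMET_CLEAVABLE, "M")), 1)
        substr(s, offset, offset) <- "M"
        substr(s, offset + 1L, offset + 1L) <- after
      }
      seqs[i] <- s
      pep_at <- function(start) substr(s, start, min(start + 9L, lens[i]))
      # database N-terminus: the expected mature form per processing rules
      if (cleav2[i]) {
        rows[[length(rows) + 1L]] <-
          new_form(genes[i], lens[i], "dbTIS", "processed", 2L, 1L, pep_at(2L))
        if (stats::runif(1) < imet_pair_fraction) {
          rows[[length(rows) + 1L]] <-
            new_form(genes[i], lens[i], "dbTIS", "retained", 1L, 1L,
                     pep_at(1L))
        }
      } else {
        rows[[length(rows) + 1L]] <-
          new_form(genes[i], lens[i], "dbTIS", "retained", 1L, 1L, pep_at(1L))
      }
      if (has_atis[i]) {
        nxt <- substr(s, offset + 1L, offset + 1L)
        if (nxt %in% IMET_CLEAVABLE) {
          rows[[length(rows) + 1L]] <-
            new_form(genes[i], lens[i], "aTIS", "processed", offset + 1L,
                     offset, pep_at(offset + 1L))
        } else {
          rows[[length(rows) + 1L]] <-
            new_form(genes[i], lens[i], "aTIS", "retained", offset,
                     offset, pep_at(offset))
        }
      }
    }
    names(seqs) <- genes
    truth <- dplyr::bind_rows(rows)
    list(sequences = seqs, truth = truth,
         params = list(n_genes = n_genes, atis_fraction = atis_fraction,
                       seed = seed, t_cc = t_cc))
  })
}

logistic_decay <- function(t, t_turn) {
  1 / (1 + exp(16 / t_turn * (t - t_turn)))
}

#' Simulate a pulsed-SILAC quantification table
#'
#' Forward model: the medium-to-light ratio decays as M/L = exp(B t) and
#' the heavy-to-light ratio rises as its complement, sampled on the
#' experimental timepoint grid with multiplicative lognormal noise per
#' channel, random missingness, a configurable fraction of monotone
#' logistic (non-exponential) decay profiles, and Poisson spectral
#' counts proportional to each proteoform's abundance.
#'
#' @param truth Truth tibble from [generate_proteome()].
#' @param timepoints Sampling times in hours, strictly positive,
#'   ascending (default the experimental grid 0.5, 1.5, 4, 8, 12, 24,
#'   48 h).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return Quantification tibble: `peptide`, `accession`, `gene`,
#'   `start`, `timepoint_h`, `intensity_L`, `intensity_M`,
#'   `intensity_H`, `ratio_ML`, `ratio_HL`, `spectral_count`,
#'   `acetylation_evidence`.
#' @export
simulate_psilac <- function(truth,
                            timepoints = c(0.5, 1.5, 4, 8, 12, 24, 48),
                            noise = noise_model(), seed = 1) {
  if (length(timepoints) == 0) stop("empty timepoint list", call. = FALSE)
  if (any(timepoints <= 0) || is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly positive and ascending",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    n <- nrow(truth)
    nonexp <- stats::runif(n) < noise$nonexp_fraction
    rows <- lapply(seq_len(n), function(i) {
      m_true <- if (nonexp[i]) {
        logistic_decay(timepoints, truth$t_turn[i])
      } else {
        exp(truth$B[i] * timepoints)
      }
      h_true <- 1 - m_true
      l0 <- 1e6
      jitter <- function(x) {
        pmax(noise$floor,
             x * stats::rlnorm(length(x), 0, noise$sigma))
      }
      li <- jitter(rep(l0, length(timepoints)))
      mi <- jitter(l0 * m_true)
      hi <- pmax(0, l0 * h_true) *
        stats::rlnorm(length(timepoints), 0, noise$sigma)
      keep <- stats::runif(length(timepoints)) >= noise$missing_prob
      spc <- stats::rpois(length(timepoints), truth$spc_mean[i])
      tibble::tibble(
        peptide = truth$peptide[i], accession = truth$accession[i],
        gene = truth$gene[i], start = truth$start[i],
        timepoint_h = timepoints, intensity_L = li, intensity_M = mi,
        intensity_H = hi, ratio_ML = mi / li, ratio_HL = hi / li,
        spectral_count = spc,
        acetylation_evidence = truth$acetylated[i]
      )[keep, ]
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate paired CHX/LTM ribosome-profiling tracks
#'
#' Builds one transcript per gene (5'UTR, CDS of 3(L+1) nt including the
#' stop codon, 3'UTR).  The cycloheximide track is Poisson background
#' over the CDS; the lactimidomycin track is a tenth of that background
#' plus planted peaks of the stated height at the first nucleotide of
#' every true initiation codon.
#'
#' @param truth Truth tibble from [generate_proteome()].
#' @param sequences Named protein sequences from the same generator
#'   call.
#' @param background_rate CHX Poisson background in reads/nt (>= 0).
#' @param peak_height LTM reads added at each planted TIS.
#' @param seed Integer seed.
#' @param utr5,utr3 UTR lengths in nt.
#' @param ltm_total,chx_total Library totals recorded on the tracks
#'   (default 1e7 mapped P-sites each).
#' @return List with `tracks` (list of [ribo_track()]), `tis_truth`
#'   (tibble: `transcript`, `position`, `category`) and `annotation`
#'   (tibble: `accession`, `transcript`, `length`, `cds_start`,
#'   `cds_end`).
#' @export
simulate_ribotracks <- function(truth, sequences, background_rate = 0.1,
                                peak_height = 50, seed = 1,
                                utr5 = 60, utr3 = 30,
                                ltm_total = 1e7, chx_total = 1e7) {
  if (background_rate < 0) stop("negative background rate", call. = FALSE)
  withr::with_seed(seed, {
    genes <- names(sequences)
    tracks <- list()
    tis_rows <- list()
    ann_rows <- list()
    for (g in genes) {
      plen <- nchar(sequences[[g]])
      cds_len <- 3L * (plen + 1L)
      len <- utr5 + cds_len + utr3
      chx <- integer(len)
      chx[(utr5 + 1):(utr5 + cds_len)] <-
        stats::rpois(cds_len, background_rate)
      ltm <- integer(len)
      ltm[(utr5 + 1):(utr5 + cds_len)] <-
        stats::rpois(cds_len, background_rate / 10)
      forms <- truth[truth$gene == g, ]
      planted <- unique(utr5 + 3L * (forms$met_position - 1L))
      ltm[planted + 1L] <- ltm[planted + 1L] + peak_height
      tx <- paste0(g, "_tx")
      tracks[[tx]] <- ribo_track(tx, chx, ltm, cds_start = utr5,
                                 cds_end = utr5 + cds_len,
                                 chx_total = chx_total,
                                 ltm_total = ltm_total)
      if (length(planted)) {
        tis_rows[[tx]] <- tibble::tibble(
          transcript = tx, position = planted,
          category = ifelse(planted == utr5, "annotated", "CDS-downstream")
        )
      }
      ann_rows[[tx]] <- tibble::tibble(
        accession = forms$accession, transcript = tx, length = len,
        cds_start = utr5, cds_end = utr5 + cds_len
      )
    }
    list(tracks = tracks, tis_truth = dplyr::bind_rows(tis_rows),
         annotation = dplyr::bind_rows(ann_rows))
  })
}

#' Generate synthetic protein complexes with planted turnover outliers
#'
#' Assigns member proteins a shared baseline turnover (uniform 5-30 h)
#' with tight within-complex spread; in a stated fraction of complexes
#' one member is shifted by `outlier_shift` hours.
#'
#' @param accessions Pool of accessions to draw members from (disjoint
#'   across complexes).
#' @param n_complexes Number of complexes.
#' @param outlier_shift Planted turnover shift in hours (default 20).
#' @param seed Integer seed.
#' @param size_range Complex size range (default 3-10 members).
#' @param outlier_fraction Fraction of complexes receiving an outlier
#'   (default 0.5).
#' @param member_sd Within-complex turnover standard deviation (h).
#' @return List with `complexes` (tibble `complex_id`, `accession`),
#'   `turnover` (named vector) and `outliers` (tibble `complex_id`,
#'   `accession` of planted outliers).
#' @export
generate_complexes <- function(accessions, n_complexes, outlier_shift = 20,
                               seed = 1, size_range = c(3, 10),
                               outlier_fraction = 0.5, member_sd = 0.5) {
  withr::with_seed(seed, {
    size_pool <- seq(size_range[1], size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_complexes,
                                  replace = TRUE)]
    if (sum(sizes) > length(accessions)) {
      stop("insufficient accessions for the requested complex sizes",
           call. = FALSE)
    }
    pool <- sample(accessions, sum(sizes))
    idx <- cumsum(c(0, sizes))
    cx_rows <- list(); out_rows <- list()
    turnover <- numeric(0)
    for (i in seq_len(n_complexes)) {
      members <- pool[(idx[i] + 1):idx[i + 1]]
      base <- stats::runif(1, 5, 30)
      tt <- base + stats::rnorm(sizes[i], 0, member_sd)
      cid <- sprintf("CPX%04d", i)
      if (outlier_shift != 0 && stats::runif(1) < outlier_fraction) {
        j <- sample(sizes[i], 1)
        tt[j] <- tt[j] + outlier_shift
        out_rows[[cid]] <- tibble::tibble(complex_id = cid,
                                          accession = members[j])
      }
      names(tt) <- members
      turnover <- c(turnover, tt)
      cx_rows[[cid]] <- tibble::tibble(complex_id = cid,
                                       accession = members)
    }
    list(complexes = dplyr::bind_rows(cx_rows), turnover = turnover,
         outliers = dplyr::bind_rows(out_rows))
  })
}
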