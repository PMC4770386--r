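#' Kinetics configuration
#'
#' Collects the constants governing turnover fitting: the cell doubling
#' time used to correct the fitted decay for dilution by cell division,
#' the goodness-of-fit gate below which the exponential model is rejected
#' in favour of linear interpolation, and the minimum number of observed
#' timepoints for a proteoform to enter the analysis at all.
#'
#' @param t_cc Cell doubling time in hours (default 24, proliferating
#'   Jurkat-like culture).
#' @param r2_threshold Minimum coefficient of determination for an
#'   exponential fit to be accepted (default 0.8).
#' @param min_timepoints Minimum number of observed timepoints per
#'   proteoform (default 3).
#' @return A `kinetics_config` list.
#' @export
#' @examples
#' kinetics_config()
#' kinetics_config(t_cc = 20)
kinetics_config <- function(t_cc = 24, r2_threshold = 0.8, min_timepoints = 3) {
  stopifnot(is.numeric(t_cc), length(t_cc) == 1, is.finite(t_cc))
  if (t_cc <= 0) stop("`t_cc` must be positive", call. = FALSE)
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1 ||
      r2_threshold <= 0 || r2_threshold > 1) {
    stop("`r2_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (min_timepoints < 2) stop("`min_timepoints` must be >= 2", call. = FALSE)
  structure(
    list(t_cc = t_cc, r2_threshold = r2_threshold,
         min_timepoints = as.integer(min_timepoints)),
    class = "kinetics_config"
  )
}

#' Normalize a pair of pulsed-SILAC ratios
#'
#' With a label swap at t = 0, the medium channel tracks pre-existing
#' (degrading) protein and the heavy channel newly synthesised protein,
#' so when M + H = L the two ratios M/L and H/L sum to one.  Measured
#' ratios are renormalised to enforce that identity: m = ml / (ml + hl)
#' and h = hl / (ml + hl).
#'
#' @param ml Non-negative M/L ratio(s).
#' @param hl Non-negative H/L ratio(s), same length as `ml`.
#' @return A list with components `m` and `h`; `m + h == 1` elementwise.
#' @export
#' @examples
#' normalize_ratios(3, 1)     # m = 0.75, h = 0.25
#' normalize_ratios(0, 2)     # m = 0,    h = 1
normalize_ratios <- function(ml, hl) {
  if (length(ml) != length(hl)) {
    stop("`ml` and `hl` must have the same length", call. = FALSE)
  }
  if (any(ml < 0, na.rm = TRUE) || any(hl < 0, na.rm = TRUE)) {
    stop("ratios must be non-negative", call. = FALSE)
  }
  tot <- ml + hl
  if (any(tot == 0, na.rm = TRUE)) {
    stop("cannot normalize: M/L and H/L are both zero", call. = FALSE)
  }
  list(m = ml / tot, h = hl / tot)
}

#' Build a normalized time course for one proteoform
#'
#' Sorts observations by time, normalizes the ratio pair at every
#' timepoint and flags observations where the raw channel sum deviates
#' strongly from the light channel (|(M+H)/L - 1| > 0.5), which the
#' normalization silently repairs but which may indicate a quantification
#' problem upstream.
#'
#' @param timepoints Observation times in hours (positive).
#' @param ml,hl Raw M/L and H/L ratios at those times.
#' @param accession Proteoform identifier.
#' @param intensity_sum_flag Optional precomputed QC flag vector.
#' @return A `time_course` list with `t`, `m`, `h`, `accession`, `qc_flag`.
#' @export
time_course <- function(timepoints, ml, hl, accession = NA_character_,
                        intensity_sum_flag = NULL) {
  stopifnot(length(timepoints) == length(ml), length(ml) == length(hl))
  keep <- is.finite(timepoints) & is.finite(ml) & is.finite(hl)
  timepoints <- timepoints[keep]; ml <- ml[keep]; hl <- hl[keep]
  if (any(timepoints <= 0)) {
    stop("timepoints must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(timepoints)) {
    stop("duplicated timepoints for accession ", accession, call. = FALSE)
  }
  o <- order(timepoints)
  nr <- normalize_ratios(ml[o], hl[o])
  flag <- if (is.null(intensity_sum_flag)) rep(FALSE, length(o)) else
    intensity_sum_flag[keep][o]
  structure(
    list(t = timepoints[o], m = nr$m, h = nr$h,
         accession = accession, qc_flag = flag),
    class = "time_course"
  )
}

#' Fit the one-parameter exponential turnover model
#'
#' Fits m(t) = exp(B t) to the normalized degradation fraction by
#' nonlinear least squares in ratio space (not log space, which would
#' reweight the noise).  The fit is initialised from the log-linear
#' slope through the origin of the positive m values and refined with
#' Levenberg-Marquardt; if that fails to converge, a bounded 1-D golden
#' section search over the sum of squares is used instead.  R-squared is
#' 1 - SS_res/SS_tot with SS_tot about the mean of the observed m.
#'
#' @param tc A [time_course()].
#' @return A list with `B` (1/h) and `r2`.
#' @export
#' @examples
#' tt <- c(0.5, 1.5, 4, 8, 12, 24, 48)
#' tc <- time_course(tt, exp(-0.05 * tt), 1 - exp(-0.05 * tt), "P1")
#' fit_exponential(tc)   # B = -0.05, r2 = 1
fit_exponential <- function(tc) {
  t <- tc$t; m <- tc$m
  if (length(unique(t)) < 2) {
    stop("need at least 2 distinct timepoints to fit", call. = FALSE)
  }
  ss_tot <- sum((m - mean(m))^2)
  if (ss_tot == 0) {
    stop("degenerate fit: constant m values (SS_tot = 0)", call. = FALSE)
  }
  # log-linear through-origin slope on positive m as starting value
  pos <- m > 0
  b0 <- if (sum(pos) >= 2) {
    sum(t[pos] * log(m[pos])) / sum(t[pos]^2)
  } else {
    -0.1
  }
  if (!is.finite(b0)) b0 <- -0.1
  sse <- function(b) sum((m - exp(b * t))^2)
  b_hat <- tryCatch({
    fit <- minpack.lm::nlsLM(
      m ~ exp(B * tt), data = list(m = m, tt = t),
      start = list(B = b0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    )
    unname(stats::coef(fit)[["B"]])
  }, error = function(e) {
    lo <- min(-10, 3 * b0); hi <- max(2, -3 * b0)
    stats::optimize(sse, c(lo, hi), tol = 1e-12)$minimum
  })
  r2 <- 1 - sse(b_hat) / ss_tot
  list(B = b_hat, r2 = r2)
}

#' 50% turnover time from the fitted decay parameter
#'
#' The degradation curve m(t) = exp(B t) crosses the synthesis curve
#' h(t) = 1 - m(t) where both equal 1/2, so the 50% turnover time is
#' ln(1/2)/B.  Defined only for a descending profile (B < 0).
#'
#' @param B Decay parameter in 1/h.
#' @return 50% turnover time in hours.
#' @export
#' @examples
#' turnover_from_B(-log(2) / 24)   # 24
turnover_from_B <- function(B) {
  stopifnot(is.numeric(B), length(B) == 1, is.finite(B))
  if (B >= 0) {
    stop("profile never reaches 1/2: B must be negative", call. = FALSE)
  }
  log(0.5) / B
}

#' 50% turnover time by linear interpolation
#'
#' Approximates the crossing of the degradation and synthesis curves
#' from the two observed M/L (and H/L) points lying on opposite sides of
#' the crossing.  Because h = 1 - m after normalization, the
#' intersection of the two chords is exactly the time where the
#' interpolated m equals 1/2.  Requires a descending trend (negative
#' Spearman correlation of m against time); when noise produces several
#' bracketing pairs the earliest is used.
#'
#' @param tc A [time_course()].
#' @return 50% turnover time in hours.
#' @export
#' @examples
#' tc <- time_course(c(8, 12), c(0.6, 0.4), c(0.4, 0.6), "P1")
#' linear_crossing(tc)   # 10
linear_crossing <- function(tc) {
  t <- tc$t; m <- tc$m
  if (length(t) < 2) stop("need at least 2 timepoints", call. = FALSE)
  rho <- suppressWarnings(stats::cor(m, t, method = "spearman"))
  if (!is.finite(rho) || rho >= 0) {
    stop("no descending trend in M/L over time", call. = FALSE)
  }
  exact <- which(m == 0.5)
  for (i in seq_len(length(t) - 1)) {
    if (length(exact) && exact[1] <= i) return(t[exact[1]])
    if (m[i] > 0.5 && m[i + 1] < 0.5) {
      return(t[i] + (m[i] - 0.5) * (t[i + 1] - t[i]) / (m[i] - m[i + 1]))
    }
  }
  if (length(exact)) return(t[exact[1]])
  stop("no pair of observations brackets the 50% crossing", call. = FALSE)
}

#' Degradation rate constant and half-life
#'
#' Separates true degradation from dilution by cell division:
#' k_deg = -B - ln(2)/t_cc, and t_1/2 = ln(2)/k_deg.  A non-positive
#' k_deg means the apparent decay is fully explained by cell growth, in
#' which case the half-life is reported as infinite.
#'
#' @param B Decay parameter (1/h), finite.
#' @param config A [kinetics_config()].
#' @return List with `k_deg` (1/h) and `t_half` (hours, possibly `Inf`).
#' @export
#' @examples
#' half_life(-2 * log(2) / 24)    # k_deg = ln(2)/24, t_half = 24
#' half_life(-log(2) / 24)        # pure dilution: t_half = Inf
half_life <- function(B, config = kinetics_config()) {
  stopifnot(is.numeric(B), length(B) == 1, is.finite(B))
  k_deg <- -B - log(2) / config$t_cc
  t_half <- if (k_deg > 0) log(2) / k_deg else Inf
  list(k_deg = k_deg, t_half = t_half)
}

#' Compute turnover for one proteoform with the full decision cascade
#'
#' Applies the filters and fallbacks in order: (1) proteoforms observed
#' in fewer than `min_timepoints` timepoints are invalid; (2) an
#' exponential fit with R-squared at or above the threshold and a
#' negative decay parameter is used directly; (3) otherwise, if the
#' profile descends and a pair of observations brackets the 50%
#' crossing, the turnover time is taken from linear interpolation;
#' (4) otherwise the proteoform remains unassigned.  The degradation
#' constant and half-life are always derived from the exponential decay
#' parameter when a fit exists, whichever method supplies the turnover
#' time.
#'
#' @param tc A [time_course()].
#' @param config A [kinetics_config()].
#' @return A `turnover_fit` list: `accession`, `n_timepoints`, `method`
#'   ("exponential", "linear" or "invalid"), `B`, `r2`, `t_turn`,
#'   `k_deg`, `t_half`.
#' @export
compute_turnover <- function(tc, config = kinetics_config()) {
  n <- length(tc$t)
  out <- list(accession = tc$accession, n_timepoints = n,
              method = "invalid", B = NA_real_, r2 = NA_real_,
              t_turn = NA_real_, k_deg = NA_real_, t_half = NA_real_)
  class(out) <- "turnover_fit"
  if (n < config$min_timepoints) return(out)
  fit <- tryCatch(fit_exponential(tc), error = function(e) NULL)
  if (!is.null(fit)) {
    out$B <- fit$B
    out$r2 <- fit$r2
    hl <- half_life(fit$B, config)
    out$k_deg <- hl$k_deg
    out$t_half <- hl$t_half
  }
  if (!is.null(fit) && fit$r2 >= config$r2_threshold && fit$B < 0) {
    out$method <- "exponential"
    out$t_turn <- turnover_from_B(fit$B)
    return(out)
  }
  t_lin <- tryCatch(linear_crossing(tc), error = function(e) NULL)
  if (!is.null(t_lin)) {
    out$method <- "linear"
    out$t_turn <- t_lin
    return(out)
  }
  out
}

#' Turnover distribution over all k-point subsets of a time course
#'
#' Re-fits the exponential model on every k-subset of the observed
#' timepoints, discards subsets whose fit falls below the R-squared
#' threshold (or does not descend), and returns the multiset of
#' resulting 50% turnover times.  Used to assess how many observations
#' the model actually needs.
#'
#' @param tc A [time_course()].
#' @param k Subset size (default 3).
#' @param config A [kinetics_config()].
#' @return Numeric vector of turnover times (possibly empty).
#' @export
subsample_turnover <- function(tc, k = 3, config = kinetics_config()) {
  n <- length(tc$t)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (n < k) stop("time course has fewer than `k` timepoints", call. = FALSE)
  subsets <- utils::combn(n, k, simplify = FALSE)
  res <- vapply(subsets, function(idx) {
    sub <- tc
    sub$t <- tc$t[idx]; sub$m <- tc$m[idx]; sub$h <- tc$h[idx]
    fit <- tryCatch(fit_exponential(sub), error = function(e) NULL)
    if (is.null(fit) || fit$r2 < config$r2_threshold || fit$B >= 0) {
      return(NA_real_)
    }
    turnover_from_B(fit$B)
  }, numeric(1))
  res[!is.na(res)]
}

#' Turnover by the exponential and the linear method side by side
#'
#' Computes the 50% turnover time for every proteoform in a
#' quantification table with both estimators independently: the
#' exponential fit (when it passes the R-squared gate with a descending
#' decay) and the linear interpolation of the bracketing pair (when one
#' exists).  Used to assess agreement between the two methods across a
#' cohort.
#'
#' @param quant Long-format quantification tibble (see
#'   [fit_turnover()]).
#' @param config A [kinetics_config()].
#' @return Tibble with `accession`, `t_turn_exp`, `t_turn_lin` (`NA`
#'   where the respective method is undefined).
#' @export
turnover_both_methods <- function(quant, config = kinetics_config()) {
  quant <- quant[is.finite(quant$ratio_ML) & is.finite(quant$ratio_HL), ]
  rows <- lapply(split(quant, quant$accession), function(d) {
    tc <- time_course(d$timepoint_h, d$ratio_ML, d$ratio_HL,
                      d$accession[1])
    t_exp <- NA_real_
    if (length(tc$t) >= config$min_timepoints) {
      fit <- tryCatch(fit_exponential(tc), error = function(e) NULL)
      if (!is.null(fit) && fit$r2 >= config$r2_threshold && fit$B < 0) {
        t_exp <- turnover_from_B(fit$B)
      }
    }
    t_lin <- tryCatch(linear_crossing(tc), error = function(e) NA_real_)
    tibble::tibble(accession = tc$accession, t_turn_exp = t_exp,
                   t_turn_lin = t_lin)
  })
  dplyr::bind_rows(rows)
}

#' Cell doubling time from a growth curve
#'
#' Fits log cell density against time by least squares; the slope is the
#' exponential growth rate r and the doubling time is ln(2)/r.
#'
#' @param densities Positive cell densities (cells/ml).
#' @param times Measurement times in hours.
#' @return Doubling time in hours.
#' @export
#' @examples
#' doubling_time(c(1, 2, 4), c(0, 24, 48))   # 24
doubling_time <- function(densities, times) {
  if (length(densities) != length(times) || length(densities) < 2) {
    stop("need >= 2 paired density/time measurements", call. = FALSE)
  }
  if (any(densities <= 0)) stop("densities must be positive", call. = FALSE)
  r <- unname(stats::coef(stats::lm(log(densities) ~ times))[["times"]])
  if (!is.finite(r) || r <= 0) {
    stop("non-positive growth rate: culture is not growing", call. = FALSE)
  }
  log(2) / r
}

#' Fit turnover for a whole quantification table
#'
#' Groups a long-format ratio table by accession, builds the normalized
#' time course for each proteoform and runs the full decision cascade.
#'
#' @param quant Tibble with columns `accession`, `timepoint_h`,
#'   `ratio_ML`, `ratio_HL` (as produced by [read_peptide_table()] or
#'   [simulate_psilac()]).
#' @param config A [kinetics_config()].
#' @return Tibble with one row per proteoform: `accession`,
#'   `n_timepoints`, `method`, `B`, `R2`, `t_turn_h`, `k_deg_per_h`,
#'   `t_half_h`.
#' @export
fit_turnover <- function(quant, config = kinetics_config()) {
  req <- c("accession", "timepoint_h", "ratio_ML", "ratio_HL")
  miss <- setdiff(req, names(quant))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  quant <- quant[is.finite(quant$ratio_ML) & is.finite(quant$ratio_HL), ]
  split_rows <- split(seq_len(nrow(quant)), quant$accession)
  rows <- lapply(names(split_rows), function(acc) {
    idx <- split_rows[[acc]]
    tc <- time_course(quant$timepoint_h[idx], quant$ratio_ML[idx],
                      quant$ratio_HL[idx], accession = acc)
    ft <- compute_turnover(tc, config)
    tibble::tibble(
      accession = acc, n_timepoints = ft$n_timepoints, method = ft$method,
      B = ft$B, R2 = ft$r2, t_turn_h = ft$t_turn,
      k_deg_per_h = ft$k_deg, t_half_h = ft$t_half
    )
  })
  dplyr::bind_rows(rows)
}
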