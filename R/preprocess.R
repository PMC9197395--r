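#' Score a trial's SCR amplitude from a conductance waveform
#'
#' Square-root-transformed base-to-peak amplitude: the base is the
#' conductance at the start of the scoring window (default 1 s after
#' stimulus onset), the peak is the maximum within the window (default up to
#' 5 s after onset), and negative deflections are clamped to zero before the
#' square root.
#'
#' @param segment Numeric vector of conductance samples (microsiemens).
#' @param onset_index Sample index of stimulus onset (1-based).
#' @param sample_rate Sampling rate in Hz.
#' @param window Scoring window in seconds after onset, `c(start, end)`.
#' @return `sqrt(max(peak - base, 0))` in sqrt-microsiemens.
#' @examples
#' seg <- c(rep(2, 1000), seq(2, 6, length.out = 4000), rep(6, 2000))
#' score_trial_amplitude(seg, onset_index = 1, sample_rate = 1000)
#' @export
score_trial_amplitude <- function(segment, onset_index, sample_rate = 1000,
                                  window = c(1, 5)) {
  stopifnot(length(window) == 2L, window[2] > window[1], window[1] >= 0)
  i0 <- onset_index + round(window[1] * sample_rate)
  i1 <- onset_index + round(window[2] * sample_rate)
  if (onset_index < 1 || i1 > length(segment)) {
    stop("waveform segment does not cover the scoring window", call. = FALSE)
  }
  base <- segment[i0]
  peak <- max(segment[i0:i1])
  sqrt(max(peak - base, 0))
}

# Linear extrapolation of leading/trailing NA runs through the two nearest
# valid points (flat carry if only one valid point exists). Values clamped
# at 0: square-root amplitudes are non-negative.
extrapolate_ends <- function(x, side = c("trailing", "leading")) {
  side <- match.arg(side)
  ok <- which(!is.na(x))
  n_extrap <- 0L
  if (length(ok) == 0L) return(list(x = x, n = 0L))
  if (side == "trailing") {
    last <- ok[length(ok)]
    if (last < length(x)) {
      idx <- (last + 1):length(x)
      if (length(ok) >= 2L) {
        i2 <- ok[length(ok) - 1L]
        slope <- (x[last] - x[i2]) / (last - i2)
      } else slope <- 0
      x[idx] <- pmax(x[last] + slope * (idx - last), 0)
      n_extrap <- length(idx)
    }
  } else {
    first <- ok[1L]
    if (first > 1L) {
      idx <- 1:(first - 1)
      if (length(ok) >= 2L) {
        i2 <- ok[2L]
        slope <- (x[i2] - x[first]) / (i2 - first)
      } else slope <- 0
      x[idx] <- pmax(x[first] + slope * (idx - first), 0)
      n_extrap <- length(idx)
    }
  }
  list(x = x, n = n_extrap)
}

#' Clean one subject's trial-level SCR series
#'
#' Applies the trial-level cleaning rules, per CS type and per phase
#' (conditioning and extinction separately):
#' \enumerate{
#'   \item within-subject outliers (`|z| >` `outlier_sd` within the
#'     (phase, CS) cell) are flagged as missing;
#'   \item the exclusion decision is made on pre-interpolation missingness:
#'     a subject is excluded if more than `max_missing_frac` (default 50%)
#'     of a phase's trial values are missing;
#'   \item interior runs of up to 3 consecutive missing values are linearly
#'     interpolated (via [zoo::na.approx()] with `maxgap = 3`); longer runs
#'     are left missing;
#'   \item trailing missing values in conditioning and leading missing
#'     values in extinction are linearly extrapolated through the two
#'     nearest valid points (flat if only one exists), clamped at 0.
#' }
#' The pre-conditioning phase is passed through untouched. Note that with
#' the task's cell sizes (10 conditioning / 8 extinction trials per CS) a
#' sample z-score cannot exceed `(n-1)/sqrt(n)` (about 2.85), so the default
#' within-subject threshold of 3 only binds for longer series; the group
#' rule ([flag_group_outliers()]) is the operative outlier check at this
#' scale.
#'
#' @param series One subject's trial data frame (`phase`, `cs`, `trial`,
#'   `scr`, optionally `missing`).
#' @param outlier_sd Within-subject outlier threshold in sample SDs.
#' @param max_missing_frac Exclusion threshold on the phase-level fraction
#'   of missing trial values (strictly greater than).
#' @return A list with `series` (cleaned copy; `missing` updated to the
#'   post-cleaning missingness) and `report`: counts of interpolated,
#'   extrapolated and outlier-flagged values, per-phase pre-interpolation
#'   missing fractions, `excluded` and `exclusion_reason`.
#' @export
clean_series <- function(series, outlier_sd = 3, max_missing_frac = 0.5) {
  stopifnot(all(c("phase", "cs", "trial", "scr") %in% names(series)))
  out <- series
  n_int <- 0L
  n_ext <- 0L
  n_out <- 0L
  miss_frac <- c(conditioning = NA_real_, extinction = NA_real_)
  for (ph in c("conditioning", "extinction")) {
    sel_ph <- which(out$phase == ph)
    if (length(sel_ph) == 0L) next
    for (cs in unique(out$cs[sel_ph])) {
      sel <- sel_ph[out$cs[sel_ph] == cs]
      sel <- sel[order(out$trial[sel])]
      x <- out$scr[sel]
      # within-subject outliers -> missing
      obs <- !is.na(x)
      if (sum(obs) >= 3L) {
        s <- stats::sd(x[obs])
        if (is.finite(s) && s > 0) {
          z <- (x - mean(x[obs])) / s
          bad <- which(obs & abs(z) > outlier_sd)
          if (length(bad)) {
            x[bad] <- NA_real_
            n_out <- n_out + length(bad)
          }
        }
      }
      out$scr[sel] <- x
    }
    miss_frac[ph] <- mean(is.na(out$scr[sel_ph]))
  }
  excluded <- any(miss_frac > max_missing_frac, na.rm = TRUE)
  reason <- if (excluded) {
    ph <- names(miss_frac)[which(miss_frac > max_missing_frac)]
    sprintf("more than %.0f%% missing trial values in %s",
            100 * max_missing_frac, paste(ph, collapse = " and "))
  } else {
    NA_character_
  }
  if (!excluded) {
    for (ph in c("conditioning", "extinction")) {
      sel_ph <- which(out$phase == ph)
      if (length(sel_ph) == 0L) next
      for (cs in unique(out$cs[sel_ph])) {
        sel <- sel_ph[out$cs[sel_ph] == cs]
        sel <- sel[order(out$trial[sel])]
        x <- out$scr[sel]
        before <- is.na(x)
        if (any(before) && any(!before)) {
          x <- zoo::na.approx(x, maxgap = 3, na.rm = FALSE)
          n_int <- n_int + sum(before & !is.na(x))
          ex <- extrapolate_ends(x, if (ph == "conditioning") "trailing" else "leading")
          x <- ex$x
          n_ext <- n_ext + ex$n
        }
        out$scr[sel] <- x
      }
    }
  }
  out$missing <- is.na(out$scr)
  list(
    series = out,
    report = list(
      n_interpolated = n_int, n_extrapolated = n_ext,
      n_outliers_within = n_out,
      missing_frac = as.list(miss_frac),
      excluded = excluded, exclusion_reason = reason
    )
  )
}

#' Flag group-level outlier subjects on per-CS mean SCR
#'
#' Subjects whose mean CS+ or mean CS- response lies beyond `threshold`
#' sample SDs of the group distribution for that CS are flagged for
#' exclusion. A zero-variance group yields no outliers, and an infinite
#' threshold is vacuous.
#'
#' @param mean_pos,mean_neg Per-subject mean CS+ and CS- SCR.
#' @param threshold Group outlier bound in SDs.
#' @return Logical vector: `TRUE` for flagged subjects.
#' @export
flag_group_outliers <- function(mean_pos, mean_neg, threshold = 3) {
  stopifnot(length(mean_pos) == length(mean_neg))
  if (length(mean_pos) < 3L) {
    stop("group outlier detection needs at least 3 subjects", call. = FALSE)
  }
  flag_one <- function(m) {
    s <- stats::sd(m, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(FALSE, length(m)))
    z <- (m - mean(m, na.rm = TRUE)) / s
    !is.na(z) & abs(z) > threshold
  }
  flag_one(mean_pos) | flag_one(mean_neg)
}

#' Clean a whole cohort and apply group-level exclusions
#'
#' Runs [clean_series()] per subject, computes per-subject mean CS+ and CS-
#' responses over conditioning and extinction, applies
#' [flag_group_outliers()], and returns the cleaned trials of retained
#' subjects together with a per-subject cleaning report.
#'
#' @param trials Cohort trial table (as in [simulate_cohort()]`$trials`).
#' @param outlier_sd Within-subject outlier threshold.
#' @param group_threshold Group outlier threshold (SDs of per-CS means).
#' @param max_missing_frac Phase-level missingness exclusion threshold.
#' @return A list: `trials` (cleaned, retained subjects only), `report`
#'   (one row per subject: cleaning counts, exclusion flags and reason).
#' @export
clean_cohort <- function(trials, outlier_sd = 3, group_threshold = 3,
                         max_missing_frac = 0.5) {
  ids <- unique(trials$subject_id)
  cleaned <- vector("list", length(ids))
  rep_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- trials[trials$subject_id == ids[i], , drop = FALSE]
    cl <- clean_series(s, outlier_sd = outlier_sd,
                       max_missing_frac = max_missing_frac)
    cleaned[[i]] <- cl$series
    r <- cl$report
    rep_rows[[i]] <- data.frame(
      subject_id = ids[i], n_interpolated = r$n_interpolated,
      n_extrapolated = r$n_extrapolated, n_outliers_within = r$n_outliers_within,
      excluded_missing = r$excluded, exclusion_reason = r$exclusion_reason,
      stringsAsFactors = FALSE
    )
  }
  report <- do.call(rbind, rep_rows)
  all_tr <- do.call(rbind, cleaned)
  keep_tr <- all_tr$phase %in% c("conditioning", "extinction")
  mpos <- tapply(all_tr$scr[keep_tr & all_tr$cs == "CS+"],
                 all_tr$subject_id[keep_tr & all_tr$cs == "CS+"],
                 mean, na.rm = TRUE)[ids]
  mneg <- tapply(all_tr$scr[keep_tr & all_tr$cs == "CS-"],
                 all_tr$subject_id[keep_tr & all_tr$cs == "CS-"],
                 mean, na.rm = TRUE)[ids]
  report$excluded_group_outlier <- if (length(ids) >= 3L) {
    flag_group_outliers(as.numeric(mpos), as.numeric(mneg),
                        threshold = group_threshold)
  } else {
    FALSE
  }
  report$excluded <- report$excluded_missing | report$excluded_group_outlier
  keep_ids <- report$subject_id[!report$excluded]
  list(trials = all_tr[all_tr$subject_id %in% keep_ids, , drop = FALSE],
       report = report)
}
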