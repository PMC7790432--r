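# Peak and bloom detection on dated abundance series, and classification of
# candidate host-parasitoid pairs into lagged (case 1, Lotka-Volterra-like)
# and simultaneous (case 2, current-infection-like) co-occurrence signatures.

# interior local maxima on the sampled grid; plateau -> first sample of the
# maximal run (value > previous, value >= next); returns integer indices
peak_indices <- function(values, min_fraction_of_max = 0.10,
                         include_endpoints = FALSE) {
  n <- length(values)
  if (n == 0) return(integer())
  vmax <- max(values)
  if (vmax <= 0) return(integer())
  cutoff <- min_fraction_of_max * vmax
  idx <- integer()
  if (n >= 3) {
    i <- 2:(n - 1)
    hit <- values[i] > values[i - 1] & values[i] >= values[i + 1] &
      values[i] >= cutoff
    idx <- i[hit]
  }
  if (include_endpoints && n >= 2) {
    if (values[1] > values[2] && values[1] >= cutoff) idx <- c(1L, idx)
    if (values[n] > values[n - 1] && values[n] >= cutoff) idx <- c(idx, n)
  }
  idx
}

#' Detect peaks in a relative-abundance series
#'
#' A peak is a local maximum on the sampled grid -- `value(i) > value(i-1)`
#' and `value(i) >= value(i+1)` (so the first sample of a flat-topped run is
#' the peak date) -- whose value is at least `min_fraction_of_max` of the
#' series maximum (the operational 10% rule that discards minor wiggles of a
#' taxon far below its own seasonal maximum). Endpoints have no two-sided
#' neighbourhood and are excluded unless `include_endpoints = TRUE`. Missing
#' values (e.g. zero-denominator samples) are dropped before detection.
#'
#' @param series an [abundance_series], or anything with `$dates`/`$values`.
#' @param min_fraction_of_max proportion of the series maximum a peak must
#'   reach (default 0.10).
#' @param include_endpoints allow one-sided peaks at the series ends.
#' @return `data.frame` with columns `date`, `value`, `fraction_of_max`.
#' @export
detect_peaks <- function(series, min_fraction_of_max = 0.10,
                         include_endpoints = FALSE) {
  dates <- as.Date(series$dates)
  values <- as.numeric(series$values)
  ok <- !is.na(values)
  dates <- dates[ok]; values <- values[ok]
  if (length(values) < 3)
    stop_validation("need at least 3 observations to detect peaks")
  vmax <- max(values)
  if (vmax <= 0)
    return(data.frame(date = as.Date(character()), value = numeric(),
                      fraction_of_max = numeric()))
  idx <- peak_indices(values, min_fraction_of_max, include_endpoints)
  data.frame(date = dates[idx], value = values[idx],
             fraction_of_max = values[idx] / vmax)
}

#' Detect blooms from peaks and absolute abundance
#'
#' A bloom is flagged either when at least `min_consecutive` peaks occur in
#' consecutive samples (allowing up to `max_gap_samples` non-peak samples
#' between successive peaks), or when the relative abundance itself reaches
#' `abs_threshold` (the "above 10%" rule for strongly blooming hosts).
#'
#' @param series the [abundance_series] the peaks came from.
#' @param peaks peak `data.frame` from [detect_peaks()].
#' @param abs_threshold relative abundance that qualifies as a bloom on its
#'   own (default 0.10).
#' @param min_consecutive minimum number of clustered peaks (default 2).
#' @param max_gap_samples maximum non-peak samples between successive peaks
#'   in a cluster (default 1).
#' @return `data.frame` with columns `start_date`, `end_date`, `n_peaks`,
#'   `trigger` (`consecutive_peaks` or `absolute_abundance`).
#' @export
detect_blooms <- function(series, peaks, abs_threshold = 0.10,
                          min_consecutive = 2, max_gap_samples = 1) {
  dates <- as.Date(series$dates)
  values <- as.numeric(series$values)
  out <- list()
  if (nrow(peaks) >= min_consecutive) {
    pidx <- match(as.Date(peaks$date), dates)
    runs <- split(pidx, cumsum(c(1, diff(pidx) > max_gap_samples + 1)))
    for (r in runs) {
      if (length(r) >= min_consecutive)
        out[[length(out) + 1]] <- data.frame(
          start_date = dates[min(r)], end_date = dates[max(r)],
          n_peaks = length(r), trigger = "consecutive_peaks")
    }
  }
  high <- which(!is.na(values) & values >= abs_threshold)
  if (length(high)) {
    runs <- split(high, cumsum(c(1, diff(high) > 1)))
    for (r in runs) {
      out[[length(out) + 1]] <- data.frame(
        start_date = dates[min(r)], end_date = dates[max(r)],
        n_peaks = sum(as.Date(peaks$date) >= dates[min(r)] &
                        as.Date(peaks$date) <= dates[max(r)]),
        trigger = "absolute_abundance")
    }
  }
  if (!length(out))
    return(data.frame(start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      n_peaks = integer(), trigger = character()))
  res <- do.call(rbind, out)
  res[order(res$start_date, res$trigger), , drop = FALSE]
}

#' Match parasitoid peaks to host peaks
#'
#' Greedy one-to-one matching mirroring the visual "a parasitoid peak
#' followed N days later" reading: parasitoid peaks are scanned in date
#' order and each is matched to the latest still-unmatched host peak lying
#' `0..max_lag_days` before it. Lags are `parasitoid date - host date` in
#' calendar days; negative lags (parasitoid first) never match.
#'
#' @param host_peaks,parasitoid_peaks peak `data.frame`s from
#'   [detect_peaks()], date-sorted.
#' @param max_lag_days matching window in days (default 14, wide enough for
#'   the 7- and 12-day delays reported for diatom-oomycete systems).
#' @return `data.frame` with columns `host_peak_date`,
#'   `parasitoid_peak_date`, `lag_days`.
#' @export
match_peaks <- function(host_peaks, parasitoid_peaks, max_lag_days = 14) {
  hd <- sort(as.Date(host_peaks$date))
  pd <- sort(as.Date(parasitoid_peaks$date))
  used <- rep(FALSE, length(hd))
  out <- list()
  for (p in seq_along(pd)) {
    lag <- as.integer(pd[p] - hd)
    cand <- which(!used & lag >= 0 & lag <= max_lag_days)
    if (length(cand)) {
      h <- cand[which.max(as.integer(hd[cand]))]   # latest eligible host peak
      used[h] <- TRUE
      out[[length(out) + 1]] <- data.frame(host_peak_date = hd[h],
                                           parasitoid_peak_date = pd[p],
                                           lag_days = lag[h])
    }
  }
  if (!length(out))
    return(data.frame(host_peak_date = as.Date(character()),
                      parasitoid_peak_date = as.Date(character()),
                      lag_days = integer()))
  do.call(rbind, out)
}

# modal value of an integer vector; ties broken towards the smallest value
modal_lag <- function(lags) {
  if (!length(lags)) return(NA_integer_)
  tab <- table(lags)
  as.integer(names(tab)[which.max(tab)])   # table() is sorted by value
}

#' Classify a candidate host-parasitoid pair
#'
#' Labels follow the two co-occurrence signatures: `case2` (simultaneous
#' appearance, lag `<= case2_tolerance_days`, default exactly 0 -- a current
#' infection) and `case1` (parasitoid peaks lagging host peaks by at least a
#' day within the window -- alternating Lotka-Volterra-like dynamics). A pair
#' can carry both labels; no matches means no label. The representative lag
#' is the modal lag among case-1 matches (ties towards the smallest lag).
#'
#' @param matches match `data.frame` from [match_peaks()].
#' @param host_peaks,parasitoid_peaks the peak tables that were matched.
#' @param case2_tolerance_days lags up to this count as simultaneous
#'   (default 0; twice-weekly sampling cannot distinguish 0 from <= 3 days,
#'   so a widened tolerance can be appropriate for sparse calendars).
#' @return list of class `pair_classification`: `labels` (character subset
#'   of `c("case1","case2")`), `representative_lag_days`, `matches`,
#'   `n_unmatched_host_peaks`, `n_unmatched_parasitoid_peaks`.
#' @export
classify_pair <- function(matches, host_peaks, parasitoid_peaks,
                          case2_tolerance_days = 0) {
  lags <- matches$lag_days
  labels <- character()
  if (any(lags <= case2_tolerance_days)) labels <- c(labels, "case2")
  case1_lags <- lags[lags > case2_tolerance_days]
  if (length(case1_lags)) labels <- c(labels, "case1")
  structure(list(
    labels = sort(labels),
    representative_lag_days = modal_lag(case1_lags),
    matches = matches,
    n_unmatched_host_peaks = nrow(host_peaks) - nrow(matches),
    n_unmatched_parasitoid_peaks = nrow(parasitoid_peaks) - nrow(matches)),
    class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("pair: %s; %d match(es); representative lag %s day(s)\n",
              if (length(x$labels)) paste(x$labels, collapse = "+") else "none",
              nrow(x$matches),
              if (is.na(x$representative_lag_days)) "-"
              else x$representative_lag_days))
  invisible(x)
}

#' Screen candidate host-parasitoid pairs
#'
#' Runs peak detection, peak matching and classification over a set of
#' candidate pairs (a supplied list, or the full host x parasitoid
#' cross-product). Output rows are sorted by number of matches (decreasing),
#' then representative lag (increasing, `NA` last), then ids, so the most
#' strongly co-occurring pairs rank first and the ordering is deterministic.
#'
#' @param host_series,parasitoid_series named lists of [abundance_series].
#' @param pairs optional two-column `data.frame` (`host_id`,
#'   `parasitoid_id`) restricting the candidate set (literature-driven
#'   candidates); default: full cross-product.
#' @param min_fraction_of_max peak rule threshold (default 0.10).
#' @param max_lag_days matching window (default 14).
#' @param case2_tolerance_days see [classify_pair()].
#' @return `data.frame` with one row per pair: `host_id`, `parasitoid_id`,
#'   `labels` (`"case1"`, `"case2"`, `"case1+case2"` or `"none"`),
#'   `representative_lag_days`, `n_matches`, `n_unmatched_host`,
#'   `n_unmatched_parasitoid`. The per-pair classification objects are
#'   attached as attribute `"classifications"`.
#' @export
screen_pairs <- function(host_series, parasitoid_series, pairs = NULL,
                         min_fraction_of_max = 0.10, max_lag_days = 14,
                         case2_tolerance_days = 0) {
  if (is.null(pairs)) {
    pairs <- expand.grid(host_id = names(host_series),
                         parasitoid_id = names(parasitoid_series),
                         stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0)
    return(data.frame(host_id = character(), parasitoid_id = character(),
                      labels = character(), representative_lag_days = integer(),
                      n_matches = integer(), n_unmatched_host = integer(),
                      n_unmatched_parasitoid = integer()))
  peak_cache <- new.env(parent = emptyenv())
  get_peaks <- function(series_list, id, tag) {
    key <- paste0(tag, "\r", id)
    if (!is.null(peak_cache[[key]])) return(peak_cache[[key]])
    pk <- detect_peaks(series_list[[id]], min_fraction_of_max)
    peak_cache[[key]] <- pk
    pk
  }
  cls <- vector("list", nrow(pairs))
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    hid <- pairs$host_id[i]; pid <- pairs$parasitoid_id[i]
    hp <- get_peaks(host_series, hid, "h")
    pp <- get_peaks(parasitoid_series, pid, "p")
    m <- match_peaks(hp, pp, max_lag_days)
    cl <- classify_pair(m, hp, pp, case2_tolerance_days)
    cls[[i]] <- cl
    rows[[i]] <- data.frame(
      host_id = hid, parasitoid_id = pid,
      labels = if (length(cl$labels)) paste(cl$labels, collapse = "+") else "none",
      representative_lag_days = cl$representative_lag_days,
      n_matches = nrow(m),
      n_unmatched_host = cl$n_unmatched_host_peaks,
      n_unmatched_parasitoid = cl$n_unmatched_parasitoid_peaks,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  ord <- order(-res$n_matches,
               ifelse(is.na(res$representative_lag_days), Inf,
                      res$representative_lag_days),
               res$host_id, res$parasitoid_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "classifications") <- cls[ord]
  res
}
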