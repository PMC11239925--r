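## Multi-electrode-array network metrics.
##
## Six well-level readouts: mean firing rate, burst frequency, burst
## duration, network asynchrony (area under the well-wide pooled
## inter-electrode cross-correlogram; 0 = perfect synchrony), network
## oscillation (ISI coefficient of variation within network bursts) and
## burst peak -- plus spike detection, the 5 spikes/min active-electrode
## filter, fixed-ISI burst detection and 20 ms network-burst binning.

#' Construct a spike-train set
#'
#' @param spikes data.frame with `well_id`, `electrode_id`, `time_s`
#'   (seconds; sorted internally, must lie in `[0, duration_s]`).
#' @param duration_s analysis window length, s (default 600).
#' @param sampling_rate acquisition rate metadata, Hz (default 12500).
#' @return data.frame of class `spike_train_set` with attributes
#'   `duration_s` and `sampling_rate`.
#' @export
spike_train_set <- function(spikes, duration_s = 600, sampling_rate = 12500) {
  .assert(all(c("well_id", "electrode_id", "time_s") %in% names(spikes)),
          "spikes needs well_id, electrode_id, time_s columns")
  .assert(all(spikes$time_s >= 0 & spikes$time_s <= duration_s),
          "spike times must lie in [0, duration_s]")
  spikes <- spikes[order(spikes$well_id, spikes$electrode_id, spikes$time_s), ,
                   drop = FALSE]
  rownames(spikes) <- NULL
  structure(spikes, class = c("spike_train_set", "data.frame"),
            duration_s = duration_s, sampling_rate = sampling_rate)
}

## split a (single-well) train set into a list of per-electrode time vectors
.trains_list <- function(trains) {
  if (inherits(trains, "spike_train_set") || is.data.frame(trains)) {
    .assert(length(unique(trains$well_id)) <= 1,
            "expected spike trains from a single well")
    split(trains$time_s, trains$electrode_id)
  } else if (is.list(trains)) trains
  else list(trains)
}

#' Detect spikes in a voltage trace by adaptive thresholding
#'
#' The noise SD is estimated robustly (1.4826 x MAD around the median); a
#' spike is a positive- or negative-going crossing of `k` times that SD,
#' with a refractory period (1 ms by default). A flat trace yields zero
#' spikes.
#'
#' @param voltage sampled voltage series.
#' @param fs sampling rate, Hz (default 12500).
#' @param k threshold multiplier (default 6).
#' @param refractory_s minimal spacing between spikes, s.
#' @return spike times in seconds (time 0 = first sample).
#' @export
detect_spikes <- function(voltage, fs = 12500, k = 6, refractory_s = 0.001) {
  .assert(fs > 0 && length(voltage) > 1, "need fs > 0 and > 1 sample")
  x <- voltage - median(voltage)
  sigma <- mad(x)
  if (sigma == 0) sigma <- .Machine$double.eps
  thr <- k * sigma
  over <- abs(x) > thr
  cross <- which(over & !c(FALSE, over[-length(over)]))
  if (length(cross) > 1) {
    gap <- refractory_s * fs
    keep <- cross[1]
    for (i in cross[-1]) if (i - keep[length(keep)] > gap) keep <- c(keep, i)
    cross <- keep
  }
  (cross - 1) / fs
}

#' Drop electrodes below the activity criterion
#'
#' Electrodes firing fewer than `min_rate_per_min` spikes per minute over the
#' analysis window are removed (the boundary is inclusive: exactly 5/min is
#' kept).
#'
#' @param trains a [spike_train_set()].
#' @param min_rate_per_min spikes per minute (default 5).
#' @return the filtered [spike_train_set()].
#' @export
filter_active_electrodes <- function(trains, min_rate_per_min = 5) {
  dur <- attr(trains, "duration_s")
  .assert(!is.null(dur), "trains must carry duration_s")
  n <- table(paste(trains$well_id, trains$electrode_id, sep = "\r"))
  rate <- n / dur * 60
  keep <- names(rate)[rate >= min_rate_per_min]
  out <- trains[paste(trains$well_id, trains$electrode_id, sep = "\r") %in% keep, ,
                drop = FALSE]
  spike_train_set(out, duration_s = dur,
                  sampling_rate = attr(trains, "sampling_rate"))
}

#' Mean firing rate of a spike train
#'
#' @param spike_times spike times, s.
#' @param duration_s analysis window, s (default 600).
#' @return rate in Hz.
#' @export
mean_firing_rate <- function(spike_times, duration_s = 600) {
  .assert(duration_s > 0, "duration_s must be > 0")
  length(spike_times) / duration_s
}

#' Fixed-ISI single-electrode burst detection
#'
#' A burst is a maximal run of consecutive spikes whose inter-spike intervals
#' are all at most `max_isi_s`, containing at least `min_spikes` spikes;
#' duration is last minus first spike time.
#'
#' @param spike_times sorted spike times, s.
#' @param max_isi_s maximal intra-burst ISI (default 0.1 s).
#' @param min_spikes minimal spikes per burst (default 5).
#' @return data.frame `start_s`, `end_s`, `n_spikes`, `duration_s`.
#' @export
detect_bursts <- function(spike_times, max_isi_s = 0.1, min_spikes = 5) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), duration_s = numeric(0))
  n <- length(spike_times)
  if (n < min_spikes) return(empty)
  .assert(!is.unsorted(spike_times), "spike_times must be sorted")
  grp <- cumsum(c(TRUE, diff(spike_times) > max_isi_s))
  runs <- split(spike_times, grp)
  runs <- runs[lengths(runs) >= min_spikes]
  if (!length(runs)) return(empty)
  data.frame(
    start_s = vapply(runs, min, 0), end_s = vapply(runs, max, 0),
    n_spikes = lengths(runs),
    duration_s = vapply(runs, function(r) max(r) - min(r), 0),
    row.names = NULL)
}

#' Summary metrics over a burst table
#'
#' @param bursts a [detect_bursts()] result.
#' @param duration_s analysis window, s.
#' @return list with `burst_frequency` (bursts/s), `mean_burst_duration_s`,
#'   `mean_spikes_per_burst` and `mean_inter_burst_interval_s` (gap from
#'   burst end to next burst start; `NA` with fewer than two bursts).
#' @export
burst_metrics <- function(bursts, duration_s) {
  .assert(duration_s > 0, "duration_s must be > 0")
  nb <- nrow(bursts)
  list(
    burst_frequency = nb / duration_s,
    mean_burst_duration_s = if (nb) mean(bursts$duration_s) else NA_real_,
    mean_spikes_per_burst = if (nb) mean(bursts$n_spikes) else NA_real_,
    mean_inter_burst_interval_s =
      if (nb >= 2) mean(bursts$start_s[-1] - bursts$end_s[-nb]) else NA_real_)
}

#' Detect well-wide network bursts
#'
#' All spikes of the well are pooled into `bin_s` bins (20 ms by default).
#' A network burst is a maximal run of occupied bins (pooled count >=
#' `min_bin_count`) spanning at least `min_bins` bins in which at least
#' `min_participation` of the electrodes fire.
#'
#' @param trains single-well [spike_train_set()] (>= 2 electrodes) or list of
#'   per-electrode spike-time vectors.
#' @param duration_s analysis window, s.
#' @param bin_s bin width, s (default 0.02).
#' @param min_participation minimal participating fraction of electrodes.
#' @param min_bins minimal run length in bins.
#' @param min_bin_count pooled spikes needed for a bin to count as occupied.
#' @return list of class `network_bursts` with `bursts` (data.frame
#'   `start_s`, `end_s`, `n_bins`, `participating`), `bin_s` and
#'   `bin_counts` (per-burst pooled per-bin counts).
#' @export
detect_network_bursts <- function(trains, duration_s = 600, bin_s = 0.02,
                                  min_participation = 0.25, min_bins = 2,
                                  min_bin_count = 1) {
  tl <- .trains_list(trains)
  .assert(length(tl) >= 2, "need >= 2 active electrodes in the well")
  nbin <- ceiling(duration_s / bin_s)
  all_t <- unlist(tl, use.names = FALSE)
  bins <- pmin(floor(all_t / bin_s) + 1L, nbin)
  counts <- tabulate(bins, nbin)
  occ <- counts >= min_bin_count
  r <- rle(occ)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  need_elec <- ceiling(min_participation * length(tl))
  bursts <- list(); bc <- list()
  for (i in which(r$values & r$lengths >= min_bins)) {
    t0 <- (starts[i] - 1) * bin_s; t1 <- ends[i] * bin_s
    part <- sum(vapply(tl, function(tt) any(tt >= t0 & tt < t1), TRUE))
    if (part >= need_elec) {
      bursts[[length(bursts) + 1]] <-
        data.frame(start_s = t0, end_s = t1,
                   n_bins = r$lengths[i], participating = part)
      bc[[length(bc) + 1]] <- counts[starts[i]:ends[i]]
    }
  }
  structure(list(
    bursts = if (length(bursts)) do.call(rbind, bursts)
             else data.frame(start_s = numeric(0), end_s = numeric(0),
                             n_bins = integer(0), participating = integer(0)),
    bin_s = bin_s, bin_counts = bc), class = "network_bursts")
}

## signed time difference from each spike in `ti` to its nearest spike in `tj`
.nearest_diff <- function(ti, tj) {
  pos <- findInterval(ti, tj)
  lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(tj))
  dlo <- ti - tj[lo]; dhi <- ti - tj[hi]
  use_lo <- pos >= 1 & (pos + 1 > length(tj) | abs(dlo) <= abs(dhi))
  ifelse(use_lo, dlo, dhi)
}

#' Network asynchrony: area under the pooled cross-correlogram
#'
#' For every ordered electrode pair the signed time difference from each
#' spike to the nearest spike of the other electrode is collected; the
#' differences within `max_lag_s` are pooled well-wide into a correlogram
#' with `bin_s` bins, which is normalized so the zero-lag bin equals 1
#' (peak-bin fallback when the zero-lag bin is empty). The asynchrony is the
#' area (sum x bin width) over the nonzero-lag bins: identical trains put
#' all mass at lag zero and score exactly 0 (perfect synchrony); larger
#' values indicate lower synchrony.
#'
#' @param trains single-well [spike_train_set()] or list of per-electrode
#'   spike-time vectors (>= 2 electrodes).
#' @param bin_s correlogram bin width, s (default 0.02).
#' @param max_lag_s maximal lag, s (default 1).
#' @return asynchrony area (s); `NA` when no pair has any coincidence within
#'   the lag window.
#' @export
asynchrony_area <- function(trains, bin_s = 0.02, max_lag_s = 1) {
  tl <- .trains_list(trains)
  .assert(length(tl) >= 2, "need >= 2 active electrodes")
  nlag <- round(max_lag_s / bin_s)
  counts <- numeric(2 * nlag + 1)
  for (i in seq_along(tl)) for (j in seq_along(tl)) {
    if (i == j || !length(tl[[i]]) || !length(tl[[j]])) next
    d <- .nearest_diff(tl[[i]], tl[[j]])
    k <- round(d / bin_s)
    k <- k[abs(k) <= nlag]
    counts <- counts + tabulate(k + nlag + 1L, 2L * nlag + 1L)
  }
  if (all(counts == 0)) return(NA_real_)
  c0 <- counts[nlag + 1]
  if (c0 == 0) c0 <- max(counts)            # peak-bin fallback
  sum(counts[-(nlag + 1)]) / c0 * bin_s
}

#' Network oscillation: mean ISI coefficient of variation within network bursts
#'
#' Per network burst the well's spikes inside the burst window are pooled and
#' sorted; the CoV (population SD / mean) of the inter-spike intervals is
#' averaged across bursts. Bursts with fewer than 3 pooled spikes are
#' skipped; `NA` when none is usable.
#'
#' @param network_bursts a [detect_network_bursts()] result.
#' @param trains the same well's trains.
#' @return mean ISI CoV (dimensionless).
#' @export
isi_cov <- function(network_bursts, trains) {
  tl <- .trains_list(trains)
  all_t <- sort(unlist(tl, use.names = FALSE))
  b <- network_bursts$bursts
  covs <- numeric(0)
  for (i in seq_len(nrow(b))) {
    tt <- all_t[all_t >= b$start_s[i] & all_t <= b$end_s[i]]
    if (length(tt) < 3) next
    isi <- diff(tt)
    if (mean(isi) == 0) next
    covs <- c(covs, .pop_sd(isi) / mean(isi))
  }
  if (!length(covs)) NA_real_ else mean(covs)
}

#' Burst peak: maximal rate of the average network burst
#'
#' Network bursts are aligned at onset, the pooled per-bin spike counts are
#' averaged across bursts (zero-padded to the longest burst), and the peak
#' of the average histogram is divided by the bin width to yield Hz.
#'
#' @param network_bursts a [detect_network_bursts()] result (>= 1 burst).
#' @return peak rate, Hz.
#' @export
burst_peak <- function(network_bursts) {
  bc <- network_bursts$bin_counts
  .assert(length(bc) >= 1, "need at least one network burst")
  len <- max(lengths(bc))
  m <- vapply(bc, function(v) c(v, rep(0, len - length(v))), numeric(len))
  avg <- if (is.matrix(m)) rowMeans(m) else mean(m)
  max(avg) / network_bursts$bin_s
}

#' All well-level MEA metrics
#'
#' Applies the active-electrode filter, computes per-electrode metrics
#' (mean firing rate, burst frequency/duration/size/IBI averaged over
#' electrodes) and well-level network metrics (asynchrony area, ISI CoV
#' within network bursts, burst peak).
#'
#' @param trains a [spike_train_set()] (one or more wells).
#' @param duration_s analysis window, s (default 600).
#' @param max_isi_s,min_spikes burst-detection parameters.
#' @param bin_s,min_participation,min_bins,min_bin_count network-burst
#'   parameters.
#' @param max_lag_s asynchrony lag window, s.
#' @param min_rate_per_min active-electrode criterion.
#' @return data.frame of class `well_metrics`, one row per well.
#' @export
well_metrics <- function(trains, duration_s = attr(trains, "duration_s") %||% 600,
                         max_isi_s = 0.1, min_spikes = 5, bin_s = 0.02,
                         min_participation = 0.25, min_bins = 2,
                         min_bin_count = 1, max_lag_s = 1,
                         min_rate_per_min = 5) {
  trains <- filter_active_electrodes(trains, min_rate_per_min)
  rows <- lapply(split(as.data.frame(trains), trains$well_id), function(wdf) {
    tl <- split(wdf$time_s, wdf$electrode_id)
    mfr <- mean(vapply(tl, mean_firing_rate, 0, duration_s = duration_s))
    bm <- lapply(tl, function(tt)
      burst_metrics(detect_bursts(tt, max_isi_s, min_spikes), duration_s))
    pick <- function(f) {
      v <- vapply(bm, `[[`, 0, f)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    if (length(tl) >= 2) {
      nb <- detect_network_bursts(tl, duration_s, bin_s, min_participation,
                                  min_bins, min_bin_count)
      async <- asynchrony_area(tl, bin_s, max_lag_s)
      cov <- isi_cov(nb, tl)
      peak <- if (nrow(nb$bursts)) burst_peak(nb) else NA_real_
    } else {
      async <- cov <- peak <- NA_real_
    }
    data.frame(
      well_id = wdf$well_id[1], n_active = length(tl),
      mean_firing_rate = mfr,
      burst_frequency = pick("burst_frequency"),
      burst_duration_s = pick("mean_burst_duration_s"),
      spikes_per_burst = pick("mean_spikes_per_burst"),
      inter_burst_interval_s = pick("mean_inter_burst_interval_s"),
      asynchrony_area = async, isi_cov = cov, burst_peak_hz = peak)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("well_metrics", "data.frame")
  out
}

#' Pre/post-treatment metric differences
#'
#' @param pre,post [well_metrics()] tables for the same wells.
#' @return data.frame of per-well differences (post minus pre).
#' @export
treatment_delta <- function(pre, post) {
  if (!setequal(pre$well_id, post$well_id))
    stop("well mismatch between recordings")
  post <- post[match(pre$well_id, post$well_id), , drop = FALSE]
  num <- vapply(pre, is.numeric, TRUE)
  delta <- as.data.frame(post[, num, drop = FALSE] - pre[, num, drop = FALSE])
  cbind(well_id = pre$well_id, delta)
}

#' Group comparison of a well metric (reporting utility)
#'
#' Thin wrapper over one-way ANOVA with Bonferroni-corrected pairwise t
#' tests, as used to compare genotypes/treatments on a metric.
#'
#' @param metrics data.frame (e.g. from [well_metrics()]).
#' @param value name of the metric column.
#' @param group name of the grouping column.
#' @return list with the `aov` fit and the pairwise comparison table.
#' @export
mea_compare <- function(metrics, value, group) {
  df <- data.frame(y = metrics[[value]], g = factor(metrics[[group]]))
  df <- df[complete.cases(df), ]
  fit <- aov(y ~ g, data = df)
  pw <- pairwise.t.test(df$y, df$g, p.adjust.method = "bonferroni")
  list(anova = fit, pairwise = pw)
}
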