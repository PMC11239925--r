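# Spike detection, burst metrics and the network-level readouts.

test_that("spike detection crosses 6 SD with a 1 ms refractory period", {
  set.seed(1)
  fs <- 12500
  v <- rnorm(fs * 2)                      # 2 s of unit noise
  tmpl <- c(4, 10, 6, 2)                  # peaks above 6 SD
  v10 <- v; v10[10000:10003] <- v10[10000:10003] - tmpl
  s <- detect_spikes(v10, fs)
  expect_equal(length(s), 1)
  expect_lt(abs(s - 9999 / fs), 1.5 / fs)
  # pure noise at 12.5 kHz for 10 s: essentially no 6-sigma crossings
  set.seed(2)
  expect_lt(length(detect_spikes(rnorm(fs * 10), fs)), 2)
  # two templates 0.5 ms apart collapse under the refractory rule
  v2 <- v; v2[10000] <- 12; v2[10000 + round(0.0005 * fs)] <- 12
  expect_equal(length(detect_spikes(v2, fs)), 1)
  expect_equal(length(detect_spikes(rep(0.5, 1000), fs)), 0)
})

test_that("the 5 spikes/min activity filter keeps the boundary", {
  mk <- function(n, e) data.frame(well_id = "w1", electrode_id = e,
                                  time_s = seq_len(n) * 600 / (n + 1))
  trains <- spike_train_set(rbind(mk(40, 1), mk(50, 2), mk(55, 3)),
                            duration_s = 600)
  kept <- filter_active_electrodes(trains)      # 4, 5, 5.5 spikes/min
  expect_setequal(unique(kept$electrode_id), c(2, 3))
  empty <- spike_train_set(data.frame(well_id = character(0),
                                      electrode_id = integer(0),
                                      time_s = numeric(0)),
                           duration_s = 600)
  expect_equal(nrow(filter_active_electrodes(empty)), 0)
})

test_that("mean firing rate is spikes over duration", {
  expect_equal(mean_firing_rate(seq_len(600), 600), 1)
  expect_equal(mean_firing_rate(numeric(0), 600), 0)
  tr <- gen_spike_trains(30, 600, "independent_poisson", rate = 2, seed = 3)
  rates <- vapply(split(tr$trains$time_s, tr$trains$electrode_id),
                  mean_firing_rate, 0, duration_s = 600)
  expect_lt(abs(mean(rates) - 2), 3 * sqrt(2 / 600 / 30))
  # linear in spike count
  expect_equal(mean_firing_rate(seq_len(1200), 600), 2)
})

test_that("fixed-ISI burst detection finds exactly the constructed bursts", {
  t1 <- c(seq(0, by = 0.01, length.out = 6),
          seq(1.05, by = 0.01, length.out = 6))
  b <- detect_bursts(t1)
  expect_equal(nrow(b), 2)
  expect_equal(b$duration_s, rep(0.05, 2))
  expect_equal(b$n_spikes, rep(6L, 2))
  expect_equal(nrow(detect_bursts(seq(0, by = 0.01, length.out = 4))), 0)
  expect_equal(nrow(detect_bursts(seq(0, 60, by = 1))), 0)
  m <- burst_metrics(b, 600)
  expect_equal(m$burst_frequency, 2 / 600)
  expect_equal(m$mean_inter_burst_interval_s, 1.05 - 0.05)
  bb <- data.frame(start_s = c(0, 11), end_s = c(1, 12),
                   n_spikes = c(10, 10), duration_s = c(1, 1))
  expect_equal(burst_metrics(bb, 600)$mean_inter_burst_interval_s, 10)
  expect_true(is.na(burst_metrics(bb[1, ], 600)$mean_inter_burst_interval_s))
  # planted-burst recovery: gaps far exceed max_isi
  tr <- gen_spike_trains(3, 120, "independent_poisson", rate = 0,
                         burst_spec = list(4, 0.01, 8), seed = 4)
  for (tt in split(tr$trains$time_s, tr$trains$electrode_id)) {
    det <- detect_bursts(tt)
    expect_equal(nrow(det), 4)
    expect_equal(det$start_s,
                 tr$true_bursts$start_s[tr$true_bursts$electrode_id == 1])
    expect_equal(det$n_spikes, rep(8L, 4))
  }
})

test_that("network bursts are recovered from planted well-wide events", {
  tr <- gen_spike_trains(8, 120, "network_bursting", rate = 0.05,
                         burst_spec = list(5, 0.01, 8),
                         network_spec = list(5, 0.003), seed = 5)
  nb <- detect_network_bursts(tr$trains, 120, min_bin_count = 3)
  expect_equal(nrow(nb$bursts), 5)
  for (i in 1:5) {
    ov <- nb$bursts$start_s[i] < tr$true_network_bursts$end_s[i] &
          nb$bursts$end_s[i] > tr$true_network_bursts$start_s[i]
    expect_true(ov)
  }
  # one spike on every electrode at the same time: single one-bin burst
  sync <- lapply(1:6, function(e) 3.01)
  nb1 <- detect_network_bursts(sync, 10, min_bins = 1)
  expect_equal(nrow(nb1$bursts), 1)
  expect_equal(nb1$bursts$n_bins, 1L)
  expect_equal(nb1$bursts$participating, 6L)
  # sparse independent firing yields no network bursts
  sp <- gen_spike_trains(8, 600, "independent_poisson", rate = 0.02, seed = 6)
  nb0 <- detect_network_bursts(sp$trains, 600, min_bin_count = 2)
  expect_equal(nrow(nb0$bursts), 0)
})

test_that("asynchrony area is zero for identical trains and grows with jitter", {
  tr <- gen_spike_trains(16, 600, "identical", rate = 1, seed = 7)
  expect_identical(asynchrony_area(tr$trains), 0)
  # independent trains: positive area, non-decreasing in the lag window
  ip <- gen_spike_trains(4, 300, "independent_poisson", rate = 1, seed = 8)
  a_half <- asynchrony_area(ip$trains, max_lag_s = 0.25)
  a_full <- asynchrony_area(ip$trains, max_lag_s = 1)
  expect_gt(a_half, 0)
  expect_gte(a_full, a_half)
  # two trains offset by exactly one bin: peak-bin fallback, area = 2 bins
  base <- seq(5, 95, by = 5)
  off <- asynchrony_area(list(base, base + 0.02), bin_s = 0.02)
  expect_equal(off, 0.04)
  # monotone in independent jitter (Spearman over a jitter grid)
  set.seed(9)
  base2 <- sort(runif(240, 0, 120))
  grid <- c(0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2)
  area <- vapply(grid, function(j) {
    tl <- lapply(1:4, function(e) sort(base2 + rnorm(240, 0, j)))
    asynchrony_area(tl)
  }, 0)
  expect_gt(cor(grid, area, method = "spearman"), 0.9)
  # invariant to electrode order and global time shifts
  tl <- split(ip$trains$time_s, ip$trains$electrode_id)
  expect_equal(asynchrony_area(tl[c(3, 1, 4, 2)]), asynchrony_area(tl))
  expect_equal(asynchrony_area(lapply(tl, `+`, 7)), asynchrony_area(tl))
})

test_that("ISI CoV is 0 for regular trains, 0.5 for the worked ISIs, 1 for Poisson", {
  reg <- fake_network_bursts(0, 10, list(rep(1, 500)))
  expect_equal(isi_cov(reg, list(seq(0, 10, by = 0.02), numeric(0))), 0)
  # ISIs {1, 1, 3, 3}: population SD 1, mean 2 -> CoV 0.5
  hand <- fake_network_bursts(0, 8, list(rep(1, 400)))
  expect_equal(isi_cov(hand, list(c(0, 1, 2, 5, 8))), 0.5)
  # exponential ISIs: CoV -> 1
  set.seed(10)
  pois <- sort(runif(2000, 0, 600))
  expo <- fake_network_bursts(0, 600, list(rep(1, 100)))
  expect_lt(abs(isi_cov(expo, list(pois)) - 1), 0.1)
  # bursts with < 3 pooled spikes are skipped
  skimpy <- fake_network_bursts(0, 1, list(1))
  expect_true(is.na(isi_cov(skimpy, list(c(0.1, 0.5)))))
})

test_that("burst peak is the aligned-average histogram maximum over bin width", {
  one <- fake_network_bursts(0, 0.06, list(c(5, 40, 10)))
  expect_equal(burst_peak(one), 40 / 0.02)
  two <- fake_network_bursts(c(0, 1), c(0.06, 1.06),
                             list(c(5, 40, 10), c(5, 40, 10)))
  expect_equal(burst_peak(two), 40 / 0.02)
  # planted triangular profiles: averaged peak matches the profile maximum
  tri <- fake_network_bursts(c(0, 1, 2), c(0.1, 1.1, 2.1),
                             list(c(2, 8, 20, 8, 2), c(4, 10, 22, 10, 4),
                                  c(3, 9, 21, 9, 3)))
  expect_equal(burst_peak(tri), 21 / 0.02)
})

test_that("well metrics assemble per-well and treatment deltas subtract", {
  tr <- gen_spike_trains(8, 600, "network_bursting", rate = 0.3,
                         burst_spec = list(6, 0.01, 10),
                         network_spec = list(6, 0.005), seed = 11)
  wm <- well_metrics(tr$trains, min_bin_count = 3)
  expect_equal(nrow(wm), 1)
  expect_true(all(wm$mean_firing_rate >= 0, wm$burst_frequency >= 0,
                  wm$asynchrony_area >= 0, wm$isi_cov >= 0))
  d0 <- treatment_delta(wm, wm)
  expect_true(all(d0[, -1] == 0, na.rm = TRUE))
  wm2 <- wm; wm2$mean_firing_rate <- wm2$mean_firing_rate + 1
  expect_equal(treatment_delta(wm, wm2)$mean_firing_rate, 1)
  wmx <- wm; wmx$well_id <- "other"
  expect_error(treatment_delta(wm, wmx), "well mismatch")
  # bicuculline-like increase in bursting shows a positive delta
  pre <- gen_spike_trains(8, 600, "independent_poisson", rate = 0.5,
                          burst_spec = list(3, 0.01, 8), seed = 12)
  post <- gen_spike_trains(8, 600, "independent_poisson", rate = 0.5,
                           burst_spec = list(12, 0.01, 8), seed = 13)
  dd <- treatment_delta(well_metrics(pre$trains), well_metrics(post$trains))
  expect_gt(dd$burst_frequency, 0)
})

test_that("group comparison utility reports ANOVA and pairwise tests", {
  set.seed(14)
  df <- data.frame(g = rep(c("WT", "KO"), each = 12),
                   mfr = c(rnorm(12, 1), rnorm(12, 3)))
  cmp <- mea_compare(df, "mfr", "g")
  expect_s3_class(cmp$anova, "aov")
  expect_lt(cmp$pairwise$p.value[1, 1], 0.01)
})
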