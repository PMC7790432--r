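test_that("peak detection finds interior local maxima above the 10% rule", {
  pk <- detect_peaks(raw_series(c(0, 5, 1, 8, 2)), min_fraction_of_max = 0.10)
  expect_equal(pk$value, c(5, 8))
  expect_equal(pk$fraction_of_max, c(5 / 8, 1))

  # strictly increasing: endpoint not eligible
  expect_identical(nrow(detect_peaks(raw_series(1:6))), 0L)
  # ... unless one-sided endpoint peaks are enabled
  expect_identical(nrow(detect_peaks(raw_series(1:6), include_endpoints = TRUE)), 1L)

  # the 10% rule discards minor local maxima
  pk <- detect_peaks(raw_series(c(0, 0.5, 0, 8, 0)))
  expect_equal(pk$value, 8)

  # plateau: first sample of a maximal run is the peak date
  pk <- detect_peaks(raw_series(c(0, 7, 7, 7, 0)))
  expect_identical(pk$date, as.Date("2016-01-02"))

  expect_error(detect_peaks(raw_series(c(1, 2))), "at least 3")
  expect_identical(nrow(detect_peaks(raw_series(c(0, 0, 0, 0)))), 0L)

  # missing observations (zero-denominator samples) are skipped
  pk <- detect_peaks(raw_series(c(0, 5, NA, 1, 8, 2)))
  expect_equal(pk$value, c(5, 8))
})

test_that("peak dates are invariant under positive rescaling of the series", {
  set.seed(21)
  for (i in 1:20) {
    v <- rpois(12, 4) * runif(12)
    if (max(v) == 0) v[3] <- 1
    base <- detect_peaks(raw_series(v))$date
    for (k in c(1e-6, 0.5, 3, 1e7)) {
      expect_identical(detect_peaks(raw_series(v * k))$date, base)
    }
  }
})

test_that("peak detection matches the brute-force triple scan on random series", {
  set.seed(8)
  for (i in 1:200) {
    v <- sample(0:3, sample(3:8, 1), replace = TRUE)
    got <- detect_peaks(raw_series(v))$date
    want <- raw_series(v)$dates[brute_force_peak_idx(v)]
    expect_identical(got, want)
  }
})

test_that("blooms arise from clustered peaks or high absolute abundance", {
  # peaks supplied on 3 consecutive samples -> one bloom
  s <- abundance_series(as.Date("2016-01-01") + 0:6,
                        c(1, 5, 5, 5, 1, 0, 0) / 1000)
  peaks <- data.frame(date = s$dates[2:4], value = s$values[2:4],
                      fraction_of_max = 1)
  bl <- detect_blooms(s, peaks)
  expect_identical(nrow(bl), 1L)
  expect_identical(bl$trigger, "consecutive_peaks")
  expect_identical(bl$n_peaks, 3L)
  expect_identical(bl$start_date, s$dates[2])

  # a single sample above 10% relative abundance is a bloom on its own
  v <- c(0.01, 0.13, 0.01, 0.02, 0.01)
  s2 <- abundance_series(as.Date("2018-03-01") + 0:4, v)
  bl2 <- detect_blooms(s2, detect_peaks(s2))
  expect_true("absolute_abundance" %in% bl2$trigger)

  # nothing clustered, nothing high: no blooms
  s3 <- abundance_series(as.Date("2016-01-01") + 0:5,
                         c(0, 0.05, 0, 0, 0.04, 0))
  lone <- detect_peaks(s3)
  expect_identical(nrow(detect_blooms(s3, lone)), 0L)

  # gap tolerance: peaks separated by one non-peak sample still cluster
  s4 <- abundance_series(as.Date("2016-01-01") + 0:6,
                         c(0, 5, 1, 5, 1, 5, 0) / 1000)
  bl4 <- detect_blooms(s4, detect_peaks(s4))
  expect_identical(bl4$trigger, "consecutive_peaks")
  expect_identical(bl4$n_peaks, 3L)
})

test_that("peak matching is greedy, one-to-one and windowed", {
  d <- function(x) as.Date("2016-01-01") + x
  hp <- data.frame(date = d(100), value = 1, fraction_of_max = 1)
  pp <- data.frame(date = d(107), value = 1, fraction_of_max = 1)
  m <- match_peaks(hp, pp)
  expect_identical(m$lag_days, 7L)

  expect_identical(match_peaks(hp, data.frame(date = d(100)))$lag_days, 0L)
  expect_identical(nrow(match_peaks(hp, data.frame(date = d(120)))), 0L)
  # negative lags (parasitoid first) never match
  expect_identical(nrow(match_peaks(hp, data.frame(date = d(95)))), 0L)

  # latest unmatched host peak within the window is preferred
  hp2 <- data.frame(date = d(c(95, 100)))
  m2 <- match_peaks(hp2, data.frame(date = d(107)))
  expect_identical(m2$host_peak_date, d(100))

  # one-to-one on random peak sets: no reuse, lags within window
  set.seed(4)
  for (i in 1:50) {
    hp3 <- data.frame(date = d(sort(sample(0:80, 6))))
    pp3 <- data.frame(date = d(sort(sample(0:80, 6))))
    m3 <- match_peaks(hp3, pp3, max_lag_days = 14)
    expect_true(all(m3$lag_days >= 0 & m3$lag_days <= 14))
    expect_identical(anyDuplicated(m3$host_peak_date), 0L)
    expect_identical(anyDuplicated(m3$parasitoid_peak_date), 0L)
  }
})

test_that("pair classification derives labels and the modal case-1 lag", {
  d <- function(x) as.Date("2016-01-01") + x
  mk <- function(lags) data.frame(host_peak_date = d(seq_along(lags) * 50),
                                  parasitoid_peak_date = d(seq_along(lags) * 50 + lags),
                                  lag_days = as.integer(lags))
  pk <- function(n) data.frame(date = d(seq_len(n)), value = 1,
                               fraction_of_max = 1)

  cl <- classify_pair(mk(c(0, 0, 7)), pk(3), pk(3))
  expect_identical(cl$labels, c("case1", "case2"))
  expect_identical(cl$representative_lag_days, 7L)

  cl2 <- classify_pair(mk(integer()), pk(2), pk(1))
  expect_identical(cl2$labels, character())
  expect_identical(cl2$n_unmatched_host_peaks, 2L)

  cl3 <- classify_pair(mk(c(7, 7, 12)), pk(3), pk(3))
  expect_identical(cl3$labels, "case1")
  expect_identical(cl3$representative_lag_days, 7L)

  # modal lag vs brute-force mode on random multisets, ties -> smallest
  set.seed(12)
  for (i in 1:50) {
    lags <- sample(1:14, sample(1:6, 1), replace = TRUE)
    tab <- table(lags)
    want <- min(as.integer(names(tab)[tab == max(tab)]))
    got <- classify_pair(mk(lags), pk(length(lags)),
                         pk(length(lags)))$representative_lag_days
    expect_identical(got, want)
  }

  # widened simultaneity tolerance reclassifies short lags
  cl4 <- classify_pair(mk(c(2)), pk(1), pk(1), case2_tolerance_days = 3)
  expect_identical(cl4$labels, "case2")
})

test_that("pair screening ranks planted responders above independent noise", {
  bump <- function(center, n = 100) dnorm(seq_len(n), center, 2)
  host_v <- 0.0001 + bump(25) + bump(70)
  responder <- 0.0001 + (bump(32) + bump(77)) / 2      # planted lag-7 response
  unrelated <- 0.0001 + bump(50) + bump(95)            # peaks >14 d from host's
  mk <- function(v) abundance_series(as.Date("2016-01-01") + 0:99, v / sum(v))
  res <- screen_pairs(list(host = mk(host_v)),
                      list(resp = mk(responder), noise = mk(unrelated)))
  expect_identical(res$parasitoid_id[1], "resp")
  expect_identical(res$labels[1], "case1")
  expect_identical(res$representative_lag_days[1], 7L)
  expect_identical(res$labels[res$parasitoid_id == "noise"], "none")

  # a pair of identical series is simultaneous at every peak
  res2 <- screen_pairs(list(h = mk(host_v)), list(p = mk(host_v)))
  expect_identical(res2$labels, "case2")
  expect_identical(res2$n_matches,
                   nrow(detect_peaks(mk(host_v))))
  expect_identical(res2$n_unmatched_host, 0L)

  # empty candidate list is an empty table, not an error
  expect_identical(nrow(screen_pairs(list(), list())), 0L)
})

test_that("noise-free daily planted pairs are recovered exactly across lags", {
  for (tau in c(0L, 3L, 14L)) {
    cfg <- scenario_config(
      phases = list(list(start = "2016-01-01", end = "2016-12-30",
                         pattern = "daily")),
      n_background_taxa = 10, bg_log_sd = 0.5,
      hosts = list(list(id = "h", centers = c("2016-03-08", "2016-06-30", "2016-10-22"),
                        width = 2, height = 60, baseline = 0.8)),
      pairs = list(list(host = "h", parasitoid = "p",
                        mode = if (tau == 0) "case2" else "case1",
                        lag_days = tau, beta = 0.5, baseline = 0.3)),
      n_persistent = 0, depth = 50000, noise_sd = 0, env_missing = "none",
      seed = 99)
    sc <- simulate_scenario(cfg)
    ser <- relative_abundance(sc$table)
    res <- screen_pairs(ser["h"], ser["p"])
    if (tau == 0) {
      expect_identical(res$labels, "case2")
    } else {
      expect_identical(res$labels, "case1")
      expect_identical(res$representative_lag_days, tau)
    }
  }
})

test_that("lags are computed on calendar dates across sampling phases", {
  # twice-weekly sampling: a Monday-to-Monday lag-7 pair is representable
  cfg <- scenario_config(
    phases = list(list(start = "2016-01-04", end = "2016-12-25",
                       pattern = "twice_weekly")),
    n_background_taxa = 10, bg_log_sd = 0.5,
    hosts = list(list(id = "h",
                      centers = c("2016-03-07", "2016-06-27", "2016-10-17"),
                      width = 2, height = 60, baseline = 0.8)),  # Mondays
    pairs = list(list(host = "h", parasitoid = "p", mode = "case1",
                      lag_days = 7, beta = 0.5, baseline = 0.3)),
    n_persistent = 0, depth = 50000, noise_sd = 0, env_missing = "none",
    seed = 5)
  sc <- simulate_scenario(cfg)
  expect_true(all(as.POSIXlt(sc$calendar)$wday %in% c(1, 4)))
  ser <- relative_abundance(sc$table)
  res <- screen_pairs(ser["h"], ser["p"])
  expect_identical(res$labels, "case1")
  expect_identical(res$representative_lag_days, 7L)
})
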