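trim <- function(x, n = 500) x[(n + 1):(length(x) - n)]

test_that("Butterworth filtering is zero-phase with the analytic response", {
  # DC through a 0.5 Hz high-pass vanishes
  dc <- recording(matrix(5, 1, 10000), 250)
  hp <- butter_filter(dc, low = 0.5)
  expect_lt(max(abs(trim(hp$data[1, ], 2500))), 5e-3)
  # 10 Hz through 0.5-125 band-pass at 500 Hz: passband, amplitude ~ 1
  s10 <- sine_recording(10, rate = 500, dur = 10, n_ch = 1)
  bp <- butter_filter(s10, 0.5, 125)
  expect_equal(max(abs(trim(bp$data[1, ]))), 1, tolerance = 0.01)
  # 40 Hz through 2-20: attenuation equals |H|^2 from the designed filter
  s40 <- sine_recording(40, rate = 250, dur = 20, n_ch = 1)
  out <- butter_filter(s40, 2, 20)
  flt <- signal::butter(2, c(2, 20) / 125, type = "pass")
  # transfer function evaluated directly at 40 Hz (frequency-domain oracle)
  zmag <- function(coefs, w) sum(coefs * exp(-1i * w * (seq_along(coefs) - 1)))
  w40 <- 2 * pi * 40 / 250
  H <- Mod(zmag(flt$b, w40) / zmag(flt$a, w40))^2
  got <- max(abs(trim(out$data[1, ], 1000)))
  expect_equal(got, H, tolerance = 0.05)
  # zero phase: cross-correlation with input peaks at lag 0
  cc <- stats::ccf(trim(s40$data[1, ], 1000), trim(out$data[1, ], 1000),
                   lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)
  expect_error(butter_filter(s40, 2, 130), "Nyquist")
})

test_that("FIR band-pass passes the band and is symmetric (zero-phase)", {
  s10 <- sine_recording(10, rate = 250, dur = 40, n_ch = 1)
  out <- fir_bandpass(s10)
  expect_equal(max(abs(trim(out$data[1, ], 2000))), 1, tolerance = 0.01)
  drift <- sine_recording(0.3, rate = 250, dur = 40, n_ch = 1)
  att <- max(abs(trim(fir_bandpass(drift)$data[1, ], 2000)))
  expect_lt(20 * log10(att), -20)
  # impulse response comes out symmetric around the impulse
  imp <- recording(matrix(c(rep(0, 3000), 1, rep(0, 2999)), 1), 250)
  y <- fir_bandpass(imp)$data[1, ]
  expect_equal(y[3001 + 1:200], y[3001 - 1:200], tolerance = 1e-9)
  expect_error(fir_bandpass(sine_recording(10, dur = 1, n_ch = 1)),
               "shorter")
})

test_that("resampling preserves sinusoids and rescales events", {
  t <- (seq_len(5000 * 4) - 1) / 5000
  rec <- recording(matrix(sin(2 * pi * 20 * t), 1), 5000,
                   events = data.frame(sample = 5000, label = "x"))
  out <- resample_recording(rec, 250)
  expect_equal(ncol(out$data), 1000L)
  expect_equal(out$events$sample, 250L)
  expect_equal(max(abs(out$data[1, 200:800])), 1, tolerance = 0.01)
  expect_identical(resample_recording(rec, 5000)$data, rec$data)
})

test_that("AAS removes a perfectly periodic artifact and errors sensibly", {
  per <- 100L; n_ep <- 40L
  shape <- sin(2 * pi * (0:(per - 1)) / per) * 50
  art <- rep(shape, n_ep)
  rec <- recording(matrix(art, 1), 250)
  trg <- as_event_selection(seq(1L, per * n_ep, by = per))
  out <- aas_correct(rec, trg, n_avg = 15)
  expect_lt(sqrt(mean(out$data^2)) / sqrt(mean(art^2)), 1e-10)
  expect_error(aas_correct(rec, as_event_selection(integer(0))), "trigger")
  irr <- as_event_selection(c(1L, 101L, 210L, 301L, 401L))
  expect_error(aas_correct(rec, irr, n_avg = 3), "irregular")
})

test_that("AAS on artifact + noise reduces artifact, bounds noise inflation", {
  set.seed(42)
  per <- 80L; n_ep <- 60L; n_avg <- 15L
  shape <- 30 * sin(2 * pi * (0:(per - 1)) / per)
  ratios <- replicate(50, {
    noise <- rnorm(per * n_ep)
    rec <- recording(matrix(rep(shape, n_ep) + noise, 1), 250)
    out <- aas_correct(rec, as_event_selection(seq(1L, per * n_ep, per)),
                       n_avg = n_avg)
    c(art = mean((out$data - noise)^2) / mean(rep(shape, n_ep)^2),
      noise = mean(out$data^2) / mean(noise^2))
  })
  expect_lt(mean(ratios["art", ]), 0.01)           # artifact mostly gone
  expect_lt(mean(ratios["noise", ]), (1 + 1 / n_avg) * 1.05)
})

test_that("CWL regression removes lagged artifact and spares clean EEG", {
  set.seed(1)
  n <- 5000
  cwl <- as.numeric(signal::filtfilt(signal::butter(2, 0.1), rnorm(n)))
  clean <- rnorm(n)
  # orthogonalize the clean signal against the lag space so the least
  # squares fit cannot absorb any of it: recovery is then exact
  L <- 5L
  lagmat <- sapply(-L:L, function(l) {
    v <- numeric(n)
    if (l >= 0) v[(1 + l):n] <- cwl[1:(n - l)]
    else v[1:(n + l)] <- cwl[(1 - l):n]
    v
  })
  clean <- clean - lagmat %*% qr.coef(qr(lagmat), clean)
  clean <- as.numeric(clean)
  build <- function(eeg) recording(rbind(eeg, cwl), 250,
                                   ch_names = c("Cz", "CWL1"),
                                   ch_types = c("eeg", "cwl"))
  # exact linear model at lag 0
  out <- cwl_regress(build(clean + 3 * cwl), max_lag_s = 0.02)
  expect_lt(max(abs(out$data[1, ] - clean)) / stats::sd(clean), 1e-6)
  expect_equal(out$ch_names, "Cz")  # CWL dropped
  # delayed coupling covered by the lag embedding
  art <- 5 * c(rep(0, 3), cwl[1:(n - 3)])
  out2 <- cwl_regress(build(clean + art), max_lag_s = 0.02)
  expect_lt(mean((out2$data[1, ] - clean)^2) / mean(art^2), 0.01)
  # orthogonal CWL: EEG essentially untouched
  out3 <- cwl_regress(build(clean), max_lag_s = 0.02)
  expect_gt(stats::cor(out3$data[1, ], clean), 0.99)
  rec_nocwl <- rand_recording(2)
  expect_error(cwl_regress(rec_nocwl), "CWL")
})

test_that("spectral segment rejection flags exactly the planted burst", {
  set.seed(2)
  n <- 250 * 60
  base <- rnorm(n)
  burst_span <- 250 * 30 + 1:(250 * 2)
  x <- base
  x[burst_span] <- x[burst_span] + 10 * sin(2 * pi * 20 * (0:(500 - 1)) / 250)
  rec <- recording(rbind(x, rnorm(n)), 250,
                   events = data.frame(sample = c(100, 250 * 30 + 100,
                                                  n - 100),
                                       label = c("a", "inburst", "b")))
  res <- reject_spectral_segments(rec, threshold_factor = 8)
  expect_equal(nrow(res$mask), 1L)
  expect_lte(res$mask$start, min(burst_span))
  expect_gte(res$mask$stop, max(burst_span))
  expect_lt(res$mask$stop - res$mask$start, 250 * 4)  # not much more
  # events: the one inside is dropped, the later one shifted
  expect_equal(res$recording$events$label, c("a", "b"))
  cut <- res$mask$stop - res$mask$start
  expect_equal(res$recording$events$sample[2], n - 100 - cut)
  # clean noise with a huge factor: identity
  clean <- recording(rbind(rnorm(n / 4), rnorm(n / 4)), 250)
  res2 <- reject_spectral_segments(clean, threshold_factor = 100)
  expect_equal(nrow(res2$mask), 0L)
  expect_equal(res2$recording$data, clean$data)
  # all-zero input: nothing exceeds a zero median strictly
  z <- recording(matrix(0, 2, 2500), 250)
  expect_equal(nrow(reject_spectral_segments(z)$mask), 0L)
})

test_that("average reference zeroes the mean, idempotently", {
  rec <- rand_recording(n_ch = 5, dur = 2)
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  out2 <- rereference_average(out)
  expect_equal(out2$data, out$data)
  shifted <- rec; shifted$data <- rec$data + 42
  expect_equal(rereference_average(shifted)$data, out$data)
})

test_that("bad channels are detected and interpolated from neighbors", {
  set.seed(3)
  n <- 2500; C <- 16
  pos <- msretest:::hemisphere_positions(C)
  src <- rnorm(n)
  data <- matrix(rep(src, C), C, byrow = TRUE) + 0.2 * rnorm(C * n)
  rec <- recording(data, 250, positions = pos)
  expect_length(bad_channels(rec)$interpolated, 0)
  # flat channel flagged
  rec2 <- rec; rec2$data[5, ] <- 0
  out <- bad_channels(rec2)
  expect_equal(out$interpolated, "ch5")
  expect_gt(stats::sd(out$recording$data[5, ]), 0)
  # plant a channel as its 4-neighbor average, corrupt it, recover it
  d <- sqrt(colSums((t(pos) - pos[1, ])^2)); d[1] <- Inf
  nn <- order(d)[1:4]
  w <- 1 / d[nn]; w <- w / sum(w)
  planted <- as.numeric(w %*% rec$data[nn, ]) + 0.01 * rnorm(n)
  rec3 <- rec; rec3$data[1, ] <- rnorm(n) * 5  # corrupted: uncorrelated
  rec3$data[1, ] <- rec3$data[1, ] - mean(rec3$data[1, ])
  fixed <- bad_channels(rec3, correlation_threshold = 0.4)
  expect_true("ch1" %in% fixed$interpolated)
  expect_gt(stats::cor(fixed$recording$data[1, ], planted), 0.95)
})

test_that("every preprocessing operation appends one provenance entry", {
  rec <- rand_recording(n_ch = 4, dur = 8)
  n0 <- length(rec$log)
  steps <- list(function(r) butter_filter(r, 1, 40),
                function(r) fir_bandpass(r, 2, 20, order = 500),
                function(r) resample_recording(r, 125),
                function(r) rereference_average(r))
  for (f in steps) {
    rec2 <- f(rec)
    expect_length(rec2$log, length(rec$log) + 1L)
    rec <- rec2
  }
})
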