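test_that("average reference zeroes the scalp mean and is idempotent", {
  mont <- tiny_montage()
  dat <- matrix(c(1, 3, 7), 3, 10, dimnames = list(mont$channels, NULL))
  rec <- apply_average_reference(recording(dat, 500, mont))
  expect_equal(unname(rec$data["A", ]), rep(-1, 10))
  expect_equal(unname(rec$data["B", ]), rep(1, 10))
  expect_equal(unname(rec$data["EOG", ]), rep(7, 10))  # ocular untouched

  # constant offset on all scalp channels vanishes; zero-mean data unchanged
  set.seed(1)
  zm <- matrix(rnorm(4 * 50), 4)
  zm[1:3, ] <- sweep(zm[1:3, ], 2, colMeans(zm[1:3, ]))
  mont4 <- montage(c("A", "B", "C", "EOG"),
                   roles = c("scalp", "scalp", "scalp", "ocular"))
  r1 <- recording(zm, 500, mont4)
  expect_equal(apply_average_reference(r1)$data, r1$data, tolerance = 1e-12)
  r2 <- recording(zm + rep(c(10, 10, 10, 0), 50), 500, mont4)
  expect_equal(apply_average_reference(r2)$data[1:3, ], r1$data[1:3, ],
               tolerance = 1e-12)

  one <- montage(c("A", "EOG"), roles = c("scalp", "ocular"))
  expect_error(apply_average_reference(
    recording(matrix(0, 2, 10), 500, one)), "at least 2 scalp")
})

test_that("band-pass keeps 10 Hz, removes DC and attenuates 100 Hz", {
  fs <- 500
  mont <- montage(c("A", "B"))
  t <- (0:4999) / fs
  dat <- rbind(sin(2 * pi * 10 * t), rep(100, length(t)))
  out <- bandpass_filter(recording(dat, fs, mont))
  mid <- 1000:4000
  expect_gt(max(abs(out$data[1, mid])), 0.95)
  expect_lt(max(abs(out$data[1, mid])), 1.05)
  expect_lt(abs(mean(out$data[2, mid])), 1)

  dat2 <- rbind(sin(2 * pi * 100 * t), sin(2 * pi * 100 * t))
  out2 <- bandpass_filter(recording(dat2, fs, mont))
  expect_lt(max(abs(out2$data[1, mid])), 0.1)

  expect_error(bandpass_filter(recording(dat, fs, mont), high = 300),
               "Nyquist")
})

test_that("epoching yields one epoch per event and the exact sample count", {
  rec <- tiny_recording(n_events = 12)
  es <- epoch_recording(rec)
  expect_identical(dim(es$epochs)[1], 12L)
  expect_identical(dim(es$epochs)[3], 400L)   # 800 ms at 500 Hz
  expect_equal(es$times_ms[1], -100)
  expect_equal(es$times_ms[400], 698)

  early <- recording(matrix(0, 3, 1000), 500, tiny_montage(),
                     events = data.frame(sample = 10L, label = "CS+"))
  expect_error(epoch_recording(early), "too close to the recording edge")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  ep <- array(5, c(2, 3, 400))
  es <- baseline_correct(make_epoch_set(ep, c("CS+", "CS-")))
  expect_true(all(es$epochs == 0))

  ep2 <- array(0, c(1, 3, 400))
  ep2[1, 1, ] <- c(rep(2, 50), rep(7, 350))   # pre mean 2, post value 7
  es2 <- baseline_correct(make_epoch_set(ep2, "CS+"))
  expect_equal(unname(es2$epochs[1, 1, 51]), 5)

  set.seed(4)
  ep3 <- array(rnorm(5 * 3 * 400), c(5, 3, 400))
  es3 <- baseline_correct(make_epoch_set(ep3, rep("CS+", 5)))
  pre <- apply(es3$epochs[, , 1:50], c(1, 2), mean)
  expect_true(all(abs(pre) < 1e-12))

  post_only <- make_epoch_set(array(0, c(1, 3, 100)), "CS+", tmin = 0,
                              tmax = 200)
  expect_error(baseline_correct(post_only), "baseline")
})

test_that("artifact rejection applies both rules on the right channels", {
  flat <- make_epoch_set(array(0, c(4, 3, 400)), rep("CS+", 4))
  expect_true(all(reject_artifacts(flat)$kept))

  spike <- flat
  spike$epochs[2, 2, 100] <- 300         # movement rule, scalp channel
  out <- reject_artifacts(spike)
  expect_identical(which(!out$kept), 2L)
  expect_identical(out$rejection_log$rule, "movement")
  expect_identical(out$rejection_log$channel, "B")

  # 60-uV step spread over 40 ms: ocular rule on EOG only
  step <- function(chan) {
    es <- make_epoch_set(array(0, c(1, 3, 400)), "CS+")
    es$epochs[1, chan, ] <- c(rep(0, 180), seq(0, 60, length.out = 20),
                              rep(60, 200))
    es
  }
  rej <- suppressWarnings(reject_artifacts(step(3)))
  expect_false(rej$kept[1])
  expect_identical(rej$rejection_log$rule, "ocular")
  expect_true(reject_artifacts(step(1))$kept[1])   # same step on scalp: kept

  no_oc <- montage(c("A", "B"))
  expect_error(reject_artifacts(flat, montage = no_oc), "ocular channel")
})

test_that("lowering rejection thresholds never keeps more trials", {
  set.seed(9)
  ep <- array(rnorm(30 * 3 * 400, sd = 40), c(30, 3, 400))
  es <- make_epoch_set(ep, rep(c("CS+", "CS-", "scenery"), 10))
  kept_prev <- Inf
  for (th in c(200, 150, 100, 60)) {
    k <- sum(suppressWarnings(
      reject_artifacts(es, ocular_uv = th, movement_uv = th))$kept)
    expect_lte(k, kept_prev)
    kept_prev <- k
  }
})

test_that("averaging obeys the 1/sqrt(n) law and errors on empty cells", {
  template <- sin(2 * pi * 5 * (0:399) / 500) * 4
  n <- 100
  set.seed(21)
  ep <- array(0, c(n, 3, 400))
  for (i in seq_len(n)) ep[i, , ] <-
    rep(template, each = 3) + rnorm(3 * 400, sd = 10)
  es <- make_epoch_set(ep, rep("CS+", n))
  erp <- average_erp(es, "s1")[["CS+"]]
  expect_identical(erp$n_trials_averaged, as.integer(n))
  resid <- sqrt(mean((erp$waveform[1, ] - template)^2))
  expect_gt(resid, 0.7)   # 10 / sqrt(100) = 1 within 30%
  expect_lt(resid, 1.3)

  es$kept[es$labels == "CS+"] <- FALSE
  expect_error(average_erp(es, "s1", conditions = "CS+"),
               "'CS\\+' has no kept trials")
})

test_that("grand average equals the mean of subject means", {
  set.seed(3)
  erps <- lapply(1:12, function(s)
    as_erp(matrix(rnorm(3 * 400), 3), subject = s))
  ga <- grand_average(erps)
  manual <- Reduce(`+`, lapply(erps, `[[`, "waveform")) / 12
  expect_equal(ga$waveform, manual)
  expect_identical(ga$subject, "grand")
})

test_that("peak detection finds planted extrema and honors tie rules", {
  t_ms <- seq(-100, 698, by = 2)
  bump <- 5 * exp(-(t_ms - 90)^2 / (2 * 15^2))
  erp <- as_erp(rbind(bump, bump, 0))
  p1 <- detect_peak(erp, "both", "P1")
  expect_lte(abs(p1$latency - 90), 2)
  expect_equal(p1$amplitude, 5, tolerance = 0.01)

  trough <- -4 * exp(-(t_ms - 140)^2 / (2 * 12^2))
  n170 <- detect_peak(as_erp(rbind(trough, trough, 0)), "both", "N170")
  expect_lte(abs(n170$latency - 140), 2)

  mono <- as_erp(rbind(-t_ms, -t_ms, 0))   # decreasing: max at window start
  expect_equal(detect_peak(mono, "both", "P1")$latency, 60)

  flat <- as_erp(matrix(2, 3, 400))        # tie: earliest latency
  expect_equal(detect_peak(flat, "both", "P1")$latency, 60)
  expect_error(detect_peak(erp, "nope", "P1"), "no group")
})

test_that("window means are exact for constants and ramps", {
  erp <- as_erp(matrix(3, 3, 400))
  expect_equal(window_mean(erp, "both", 200, 300), 3)
  expect_equal(window_mean(erp, "both", -100, 0), 3)

  t_ms <- seq(-100, 698, by = 2)
  ramp <- as_erp(rbind(t_ms * 0.01, t_ms * 0.01, 0))
  expect_equal(window_mean(ramp, "both", 600, 700), 6.49, tolerance = 1e-6)

  zero <- as_erp(matrix(0, 3, 400))
  expect_equal(window_mean(zero, "both", 600, 700), 0)
  expect_error(window_mean(erp, "both", 600, 900), "outside the epoch")
})

test_that("erp_metrics exports a tidy table of peaks and window means", {
  erp <- as_erp(matrix(1, 3, 400))
  tab <- erp_metrics(list(erp), groups = "both")
  expect_identical(nrow(tab), 7L)          # P1, N170 and 5 late windows
  expect_setequal(unique(tab$measure),
                  c("P1", "N170", sprintf("mean_%d_%d", seq(200, 600, 100),
                                          seq(300, 700, 100))))
})
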