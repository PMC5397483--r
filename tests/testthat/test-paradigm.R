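# Stimulus construction: triplet grammar, perturbations, designs, audio.

test_that("triplet sequences follow the ABA_ grammar and 12-TET arithmetic", {
  tl <- make_triplet_sequence(6, 7, 420)
  expect_s3_class(tl, "stimulus_timeline")
  expect_equal(nrow(tl$events), 18)
  expect_equal(tl$total_ms, 2400)
  # onsets mod 400 in {0, 100, 200}, labels cycle A,B,A
  expect_true(all(tl$events$onset_ms %% 400 %in% c(0, 100, 200)))
  expect_equal(tl$events$label, rep(c("A", "B", "A"), 6))
  expect_true(all(tl$events$duration_ms == 100))
  # B frequency is df semitones above base
  b <- unique(tl$events$freq_hz[tl$events$label == "B"])
  expect_equal(b, 420 * 2^(7 / 12))
  # further printed durations
  expect_equal(make_triplet_sequence(3, 4, 420)$total_ms, 1200)
  expect_equal(make_triplet_sequence(10, 10, 500)$total_ms, 4000)
  # 12-TET example: 10 st above 420 Hz
  tl10 <- make_triplet_sequence(1, 10, 420)
  expect_equal(tl10$events$freq_hz[2], 420 * 2^(10 / 12), tolerance = 1e-12)
  expect_equal(round(tl10$events$freq_hz[2], 1), 748.4)
})

test_that("st/Hz conversions round-trip to 1e-9 relative error", {
  st <- c(-14.3, -2, 0, 0.5, 4, 7, 10, 15.25)
  hz <- st_to_hz(st, 420)
  expect_equal(hz_to_st(hz, 420), st, tolerance = 1e-9)
  expect_equal(st_to_hz(12, 440), 880)
})

test_that("invalid triplet-sequence inputs are rejected with the field named", {
  expect_error(make_triplet_sequence(0, 7, 420), "n_triplets")
  expect_error(make_triplet_sequence(5, -1, 420), "df_st")
  expect_error(make_triplet_sequence(5, 7, 0), "base_freq_hz")
})

test_that("apply_pause shifts later events, is removable, and rejects bad bounds", {
  tl <- make_triplet_sequence(10, 7, 420)
  tp <- apply_pause(tl, 600, 7)
  expect_equal(tp$total_ms, 4600)
  early <- tl$events$onset_ms < 2800
  expect_equal(tp$events$onset_ms[early], tl$events$onset_ms[early])
  expect_equal(tp$events$onset_ms[!early], tl$events$onset_ms[!early] + 600)
  # removing the shift reproduces the original bit-exactly
  rec <- tp
  rec$events$onset_ms[!early] <- rec$events$onset_ms[!early] - 600L
  expect_identical(rec$events, tl$events)
  # zero pause is the identity
  expect_identical(apply_pause(tl, 0, 7), tl)
  # 300 ms pause shifts test-triplet onsets by exactly 300
  tq <- apply_pause(tl, 300, 7)
  expect_equal(tq$events$onset_ms[!early] - tl$events$onset_ms[!early],
               rep(300, sum(!early)))
  expect_error(apply_pause(tl, 300, 10), "after_triplet")
  expect_error(apply_pause(tl, -5, 7), "pause_ms")
})

test_that("apply_distractor centers the tone in the gap and moves nothing else", {
  tl <- make_triplet_sequence(6, 10, 420)
  td <- apply_distractor(tl, "B+2", 3)
  expect_equal(nrow(td$events), nrow(tl$events) + 1)
  d <- td$events[td$events$label == "distractor", ]
  # gap after triplet 3 spans 1100-1200 ms; 50 ms tone -> margins 25 ms
  expect_equal(d$onset_ms, 1125)
  expect_equal(d$duration_ms, 50)
  expect_equal(d$freq_hz, 420 * 2^(12 / 12))
  expect_identical(td$events[td$events$label != "distractor", c("onset_ms", "freq_hz")],
                   tl$events[, c("onset_ms", "freq_hz")],
                   ignore_attr = TRUE)
  # B+0 equals the B frequency
  d0 <- apply_distractor(tl, "B+0", 3)
  expect_equal(d0$events$freq_hz[d0$events$label == "distractor"],
               420 * 2^(10 / 12))
  # (A+B)/2 is the log midpoint = geometric mean
  dm <- apply_distractor(tl, "(A+B)/2", 3)
  fm <- dm$events$freq_hz[dm$events$label == "distractor"]
  expect_equal(fm, 420 * 2^(5 / 12))
  expect_equal(fm, sqrt(420 * 420 * 2^(10 / 12)), tolerance = 1e-12)
  expect_error(apply_distractor(tl, "B+2", 3, dur_ms = 150), "gap")
})

test_that("apply_deviant changes one field of one event and nothing else", {
  tl <- make_triplet_sequence(6, 7, 420)
  tv <- apply_deviant(tl, 2, 3)
  expect_equal(nrow(tv$events), nrow(tl$events))
  changed <- which(tv$events$freq_hz != tl$events$freq_hz |
                     tv$events$label != tl$events$label)
  expect_length(changed, 1)
  expect_equal(tv$events$label[changed], "deviant")
  expect_equal(tv$events$onset_ms[changed], 900)  # B of triplet 3
  expect_equal(tv$events$freq_hz[changed], 420 * 2^(9 / 12), tolerance = 1e-12)
  expect_equal(tv$events$onset_ms, tl$events$onset_ms)
  # offset 0: frequency unchanged, label still deviant
  t0 <- apply_deviant(tl, 0, 3)
  expect_equal(t0$events$freq_hz, tl$events$freq_hz)
  expect_equal(sum(t0$events$label == "deviant"), 1)
  expect_error(apply_deviant(tl, 2, 9), "in_triplet")
})

test_that("roved base frequencies form the printed ladder", {
  lad <- rove_ladder()
  expect_length(lad, 5)
  expect_equal(lad[1], 420)
  expect_equal(lad[5], 1060)
  # geometrically even, ~4 st steps
  steps <- 12 * diff(log2(lad))
  expect_equal(steps, rep(steps[1], 4), tolerance = 1e-12)
  expect_equal(steps[1], 4, tolerance = 0.01)
  # maximum B frequency at DF = 10 matches the printed 1888 Hz (truncated)
  expect_equal(trunc(max(lad) * 2^(10 / 12)), 1888)
  # draws: in range, ladder members, seed-deterministic, RNG untouched
  f1 <- rove_base_frequency(42)
  expect_identical(f1, rove_base_frequency(42))
  draws <- vapply(1:50, rove_base_frequency, numeric(1))
  expect_true(all(draws >= 420 & draws <= 1060))
  expect_true(all(draws %in% lad))
  expect_gt(length(unique(draws)), 1)
})

test_that("pause experiment design enumerates the full factorial", {
  d <- pause_experiment_design(20)
  expect_equal(nrow(d), 300)
  expect_equal(nrow(unique(d[, c("df_st", "cell")])), 15)
  expect_setequal(unique(d$df_st), c(4, 7, 10))
  expect_equal(nrow(pause_experiment_design(1)), 15)
  expect_error(pause_experiment_design(0), "repetitions")
  # realized durations: pause rows extend the 4 s ten-triplet stimulus
  row <- d[d$cell == "7T+pause600+3T" & d$df_st == 7, ][1, ]
  expect_equal(timeline_from_design_row(row)$total_ms, 4600)
})

test_that("perturbation experiment design crosses DF with controls and cells", {
  cells <- c("disB+2", "disAB", "dev+2")
  d <- perturbation_experiment_design(cells, 20)
  expect_equal(nrow(d), 3 * (2 + 3) * 20)
  expect_equal(nrow(perturbation_experiment_design(cells, 1)), 15)
  expect_warning(perturbation_experiment_design(character(0), 1), "controls")
  expect_equal(nrow(suppressWarnings(perturbation_experiment_design(character(0), 1))), 6)
  # durations: 6-triplet rows 2400 ms, 3-triplet rows 1200 ms
  durs <- vapply(seq_len(nrow(d)), function(i)
    timeline_from_design_row(d[i, ])$total_ms, numeric(1))
  expect_true(all(durs[d$n_triplets == 6] == 2400))
  expect_true(all(durs[d$n_triplets == 3] == 1200))
  expect_error(perturbation_experiment_design("bogus", 1), "bogus")
})

test_that("waveform synthesis places ramped tones on silence", {
  tl <- make_triplet_sequence(2, 7, 420)
  w <- synthesize_waveform(tl, sample_rate = 44100)
  expect_length(w, 800 * 44.1)
  # silent gap (300-400 ms of each triplet) is exactly zero
  gap <- w[(0.305 * 44100):(0.395 * 44100)]
  expect_true(all(gap == 0))
  # tone support of a 100 ms tone at 44.1 kHz is 4410 samples
  expect_gt(sum(w[1:4410] != 0), 4300)
  expect_gt(max(abs(w[(0.402 * 44100):(0.41 * 44100)])), 0)  # next triplet's A tone
  # envelope midpoint is full scale: amplitude near 0.5 for default level
  seg <- w[2000:2500]
  expect_equal(max(abs(seg)), 0.5, tolerance = 0.01)
  expect_error(synthesize_waveform(tl, 44100, ramp_ms = 60), "ramp")
  expect_error(synthesize_waveform(tl, 4000), "sample_rate")
})

test_that("WAV writer produces a parseable RIFF header", {
  tl <- make_triplet_sequence(1, 7, 420)
  w <- synthesize_waveform(tl, sample_rate = 8000)
  f <- tempfile(fileext = ".wav")
  write_wav(w, f, format = "pcm16")
  con <- file(f, "rb")
  hdr <- readChar(con, 4)
  invisible(readBin(con, integer(), 1, size = 4))
  wave <- readChar(con, 4)
  close(con)
  expect_equal(hdr, "RIFF")
  expect_equal(wave, "WAVE")
  expect_equal(file.size(f), 44 + 2 * length(w))
  unlink(f)
})

test_that("timelines round-trip through JSON", {
  tl <- apply_distractor(make_triplet_sequence(6, 7, 420), "B+2", 3)
  js <- timeline_to_json(tl)
  tl2 <- timeline_from_json(js)
  expect_equal(tl2$events, tl$events)
  expect_equal(tl2$total_ms, tl$total_ms)
  expect_equal(tl2$perturbation$freq_spec, "B+2")
})
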