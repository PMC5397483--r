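# Stimulus construction: ABA_ triplet timelines, perturbations, designs, audio.

TRIPLET_MS <- 400L
TONE_MS <- 100L

#' Semitone/frequency conversion (12-tone equal temperament)
#'
#' `st_to_hz()` returns the frequency `st` semitones above `ref_hz`;
#' `hz_to_st()` is its inverse. One semitone is a factor of 2^(1/12).
#'
#' @param st offset in semitones (may be negative).
#' @param hz,ref_hz frequencies in Hz.
#' @return a numeric vector of frequencies (Hz) or offsets (st).
#' @export
st_to_hz <- function(st, ref_hz) ref_hz * 2^(st / 12)

#' @rdname st_to_hz
#' @export
hz_to_st <- function(hz, ref_hz) 12 * log2(hz / ref_hz)

new_timeline <- function(events, total_ms, df_st, base_freq_hz,
                         perturbation = list(type = "none")) {
  structure(
    list(events = events, total_ms = as.integer(total_ms), df_st = df_st,
         base_freq_hz = base_freq_hz, perturbation = perturbation),
    class = "stimulus_timeline"
  )
}

#' @export
print.stimulus_timeline <- function(x, ...) {
  cat(sprintf(
    "<stimulus_timeline> %d events, %d ms, DF = %g st, base = %g Hz, perturbation: %s\n",
    nrow(x$events), x$total_ms, x$df_st, x$base_freq_hz, x$perturbation$type))
  invisible(x)
}

#' Build an ABA_ triplet sequence
#'
#' Constructs the timeline of a repeating ABA_ triplet stimulus: within each
#' 400 ms triplet, a low A tone (100 ms), a high B tone (100 ms), a second A
#' tone (100 ms), then 100 ms of silence. The B tone lies `df_st` semitones
#' above the A tone.
#'
#' @param n_triplets number of triplets (>= 1).
#' @param df_st frequency difference between A and B tones, in semitones (> 0).
#' @param base_freq_hz A-tone frequency in Hz (> 0).
#' @return a `stimulus_timeline`: an events table (onset_ms, duration_ms,
#'   freq_hz, label) plus total duration and metadata. Total duration is
#'   exactly `400 * n_triplets` ms (the final triplet keeps its trailing
#'   silence).
#' @examples
#' tl <- make_triplet_sequence(6, df_st = 7, base_freq_hz = 420)
#' tl$total_ms  # 2400
#' @export
make_triplet_sequence <- function(n_triplets, df_st, base_freq_hz) {
  if (!is.numeric(n_triplets) || length(n_triplets) != 1L || n_triplets < 1)
    stop("n_triplets must be a single count >= 1", call. = FALSE)
  if (!is.numeric(df_st) || length(df_st) != 1L || df_st <= 0)
    stop("df_st must be a single positive semitone difference", call. = FALSE)
  if (!is.numeric(base_freq_hz) || length(base_freq_hz) != 1L || base_freq_hz <= 0)
    stop("base_freq_hz must be a single positive frequency", call. = FALSE)
  n_triplets <- as.integer(n_triplets)
  freq_b <- st_to_hz(df_st, base_freq_hz)
  trip0 <- (seq_len(n_triplets) - 1L) * TRIPLET_MS
  events <- data.frame(
    onset_ms    = as.integer(as.vector(vapply(trip0, function(t0) t0 + c(0L, 100L, 200L), integer(3)))),
    duration_ms = rep(TONE_MS, 3L * n_triplets),
    freq_hz     = rep(c(base_freq_hz, freq_b, base_freq_hz), n_triplets),
    label       = rep(c("A", "B", "A"), n_triplets),
    stringsAsFactors = FALSE
  )
  new_timeline(events, TRIPLET_MS * n_triplets, df_st, base_freq_hz)
}

n_triplets_of <- function(timeline) sum(timeline$events$label %in% c("A", "B", "deviant")) %/% 3L

#' Insert a silent pause into a triplet sequence
#'
#' Shifts every event after the chosen triplet boundary later by `pause_ms`,
#' lengthening the stimulus by the same amount. A zero-length pause returns
#' an identical timeline.
#'
#' @param timeline a `stimulus_timeline`.
#' @param pause_ms pause duration in ms (>= 0).
#' @param after_triplet insert the pause after this triplet (1-based; must be
#'   strictly before the last triplet).
#' @return the modified `stimulus_timeline`.
#' @export
apply_pause <- function(timeline, pause_ms, after_triplet) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  n <- n_triplets_of(timeline)
  if (!is.numeric(pause_ms) || pause_ms < 0)
    stop("pause_ms must be >= 0", call. = FALSE)
  if (after_triplet < 1 || after_triplet >= n)
    stop(sprintf("after_triplet must lie in [1, %d)", n), call. = FALSE)
  if (pause_ms == 0) return(timeline)
  boundary <- as.integer(after_triplet) * TRIPLET_MS
  ev <- timeline$events
  late <- ev$onset_ms >= boundary
  ev$onset_ms[late] <- ev$onset_ms[late] + as.integer(pause_ms)
  out <- new_timeline(ev, timeline$total_ms + as.integer(pause_ms),
                      timeline$df_st, timeline$base_freq_hz,
                      list(type = "pause", pause_ms = as.integer(pause_ms),
                           after_triplet = as.integer(after_triplet)))
  out
}

#' Resolve a semitone-relative frequency specification
#'
#' Specifications are relative to the current A and B tones: `"A"`, `"B"`,
#' `"A-2"`, `"B+2"`, or `"(A+B)/2"` (alias `"AB"`), the log-frequency
#' midpoint (geometric mean in Hz) of A and B. Arithmetic is 12-tone equal
#' temperament throughout.
#'
#' @param spec a specification string.
#' @param df_st A-to-B distance in semitones.
#' @param base_freq_hz A-tone frequency in Hz.
#' @return frequency in Hz.
#' @export
resolve_freq_spec <- function(spec, df_st, base_freq_hz) {
  st <- freq_spec_st(spec, df_st)
  st_to_hz(st, base_freq_hz)
}

# semitone position (relative to A) of a frequency spec
freq_spec_st <- function(spec, df_st) {
  spec <- gsub("\\s", "", spec)
  if (spec %in% c("(A+B)/2", "AB")) return(df_st / 2)
  m <- regmatches(spec, regexec("^([AB])([+-][0-9.]+)?$", spec))[[1]]
  if (length(m) == 0)
    stop(sprintf("cannot parse frequency spec '%s'", spec), call. = FALSE)
  anchor <- if (m[2] == "A") 0 else df_st
  offset <- if (nzchar(m[3])) as.numeric(m[3]) else 0
  anchor + offset
}

#' Insert a distractor tone into an inter-triplet gap
#'
#' Centers a short extra tone in the 100 ms silent gap ("_") that ends the
#' chosen triplet, leaving equal silent margins on either side. No other
#' event moves.
#'
#' @param timeline a `stimulus_timeline`.
#' @param freq_spec frequency specification (see [resolve_freq_spec()]).
#' @param after_triplet place the distractor in the gap ending this triplet.
#' @param dur_ms distractor duration in ms (default 50; must fit the gap).
#' @return the modified `stimulus_timeline` with one extra event.
#' @export
apply_distractor <- function(timeline, freq_spec, after_triplet, dur_ms = 50) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  n <- n_triplets_of(timeline)
  if (after_triplet < 1 || after_triplet > n)
    stop(sprintf("after_triplet must lie in [1, %d]", n), call. = FALSE)
  gap_len <- TONE_MS
  if (dur_ms > gap_len)
    stop(sprintf("dur_ms (%g) exceeds the %d ms inter-triplet gap", dur_ms, gap_len),
         call. = FALSE)
  gap_start <- as.integer(after_triplet) * TRIPLET_MS - gap_len
  margin <- (gap_len - dur_ms) / 2
  ev <- timeline$events
  new_ev <- data.frame(
    onset_ms = as.integer(gap_start + margin), duration_ms = as.integer(dur_ms),
    freq_hz = resolve_freq_spec(freq_spec, timeline$df_st, timeline$base_freq_hz),
    label = "distractor", stringsAsFactors = FALSE)
  ev <- rbind(ev, new_ev)
  ev <- ev[order(ev$onset_ms), , drop = FALSE]
  rownames(ev) <- NULL
  new_timeline(ev, timeline$total_ms, timeline$df_st, timeline$base_freq_hz,
               list(type = "distractor", freq_spec = freq_spec,
                    after_triplet = as.integer(after_triplet),
                    dur_ms = dur_ms))
}

#' Replace a triplet's B tone with a frequency deviant
#'
#' Shifts the B tone of the chosen triplet by `offset_st` semitones and
#' relabels it `"deviant"`. Timing and event count are unchanged.
#'
#' @param timeline a `stimulus_timeline`.
#' @param offset_st frequency offset in semitones relative to the B tone.
#' @param in_triplet which triplet's B tone to replace (1-based).
#' @return the modified `stimulus_timeline`.
#' @export
apply_deviant <- function(timeline, offset_st, in_triplet) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  n <- n_triplets_of(timeline)
  if (in_triplet < 1 || in_triplet > n)
    stop(sprintf("in_triplet must lie in [1, %d]", n), call. = FALSE)
  ev <- timeline$events
  idx <- which(ev$label == "B" &
                 ev$onset_ms == (as.integer(in_triplet) - 1L) * TRIPLET_MS + TONE_MS)
  if (length(idx) != 1L)
    stop(sprintf("triplet %d has no standard B tone to replace", in_triplet),
         call. = FALSE)
  ev$freq_hz[idx] <- ev$freq_hz[idx] * 2^(offset_st / 12)
  ev$label[idx] <- "deviant"
  new_timeline(ev, timeline$total_ms, timeline$df_st, timeline$base_freq_hz,
               list(type = "deviant", offset_st = offset_st,
                    in_triplet = as.integer(in_triplet)))
}

#' Roved base-frequency ladder
#'
#' The A-tone base frequency is roved from trial to trial over a fixed
#' five-rung ladder spanning 420-1060 Hz in geometrically even steps of
#' approximately 4 semitones.
#'
#' @return numeric vector of ladder frequencies in Hz, ascending.
#' @export
rove_ladder <- function() {
  lo <- 420; hi <- 1060
  lo * (hi / lo)^((0:4) / 4)
}

#' Draw a roved base frequency
#'
#' Picks one rung of [rove_ladder()] uniformly at random. The same seed
#' always yields the same frequency; the global RNG state is untouched.
#'
#' @param rng_seed integer seed.
#' @return one frequency in Hz.
#' @export
rove_base_frequency <- function(rng_seed) {
  ladder <- rove_ladder()
  ladder[with_local_seed(rng_seed, sample.int(length(ladder), 1L))]
}

# evaluate expr under a temporary RNG seed, restoring global state after
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Pause-experiment design table
#'
#' Enumerates the factorial pause paradigm: DF in \{4, 7, 10\} st crossed
#' with five stimulus-length/pause cells (3, 7 or 10 triplets without pause;
#' 7 context triplets followed by a 300 or 600 ms pause and 3 test triplets),
#' each repeated `repetitions` times.
#'
#' @param repetitions repetitions per condition (default 20).
#' @return a data.frame with one row per trial: experiment, df_st,
#'   n_triplets, pause_ms, after_triplet, cell, repetition.
#' @export
pause_experiment_design <- function(repetitions = 20) {
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  cells <- data.frame(
    cell = c("3T", "7T", "10T", "7T+pause300+3T", "7T+pause600+3T"),
    n_triplets = c(3L, 7L, 10L, 10L, 10L),
    pause_ms = c(0L, 0L, 0L, 300L, 600L),
    after_triplet = c(NA_integer_, NA_integer_, NA_integer_, 7L, 7L),
    stringsAsFactors = FALSE)
  grid <- expand.grid(rep = seq_len(as.integer(repetitions)),
                      cell_i = seq_len(nrow(cells)), df_st = c(4, 7, 10))
  out <- cbind(experiment = "pause", df_st = grid$df_st,
               cells[grid$cell_i, , drop = FALSE],
               repetition = grid$rep)
  rownames(out) <- NULL
  out
}

parse_perturbation_cell <- function(cell) {
  cell <- gsub("\\s", "", cell)
  if (grepl("^dis", cell)) {
    spec <- sub("^dis", "", cell)
    if (spec == "AB") spec <- "(A+B)/2"
    list(type = "distractor", freq_spec = spec, cell = cell)
  } else if (grepl("^dev(iant)?", cell)) {
    off <- sub("^dev(iant)?", "", cell)
    if (!nzchar(off)) stop(sprintf("deviant cell '%s' needs an offset, e.g. dev+2", cell),
                           call. = FALSE)
    list(type = "deviant", offset_st = as.numeric(off), cell = cell)
  } else {
    stop(sprintf("cannot parse perturbation cell '%s' (expected dis<spec> or dev<offset>)",
                 cell), call. = FALSE)
  }
}

#' Perturbation-experiment design table
#'
#' Enumerates the distractor/deviant paradigm: DF in \{4, 7, 10\} st crossed
#' with two controls (3 and 6 unperturbed triplets) plus the requested
#' perturbation cells (6 triplets each, perturbation tied to the third
#' triplet), repeated `repetitions` times.
#'
#' @param perturbation_cells character vector of cell names: `"dis<spec>"`
#'   for a distractor (e.g. `"disB+2"`, `"disAB"`, `"disA-2"`) or
#'   `"dev<offset>"` for a deviant (e.g. `"dev+2"`).
#' @param repetitions repetitions per condition.
#' @return a data.frame with one row per trial.
#' @export
perturbation_experiment_design <- function(perturbation_cells, repetitions = 20) {
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  if (length(perturbation_cells) == 0)
    warning("no perturbation cells given; design contains controls only")
  else
    lapply(perturbation_cells, parse_perturbation_cell)  # validate early
  cells <- c("3T", "6T", as.character(perturbation_cells))
  grid <- expand.grid(rep = seq_len(as.integer(repetitions)),
                      cell = cells, df_st = c(4, 7, 10),
                      stringsAsFactors = FALSE)
  out <- data.frame(
    experiment = "perturbation", df_st = grid$df_st, cell = grid$cell,
    n_triplets = ifelse(grid$cell == "3T", 3L, 6L),
    perturbation = ifelse(grid$cell %in% c("3T", "6T"), "none", grid$cell),
    repetition = grid$rep, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Realize a design row as a stimulus timeline
#'
#' Maps one row of a design table to its `stimulus_timeline`: pauses are
#' inserted at the stated boundary; distractors go in the gap after the
#' third triplet and deviants replace the third triplet's B tone.
#'
#' @param row a single-row data.frame from a design table.
#' @param base_freq_hz A-tone base frequency in Hz.
#' @return a `stimulus_timeline`.
#' @export
timeline_from_design_row <- function(row, base_freq_hz = 420) {
  tl <- make_triplet_sequence(row$n_triplets, row$df_st, base_freq_hz)
  if (!is.null(row$pause_ms) && !is.na(row$pause_ms) && row$pause_ms > 0) {
    tl <- apply_pause(tl, row$pause_ms, row$after_triplet)
  } else if (!is.null(row$perturbation) && !is.na(row$perturbation) &&
             row$perturbation != "none") {
    p <- parse_perturbation_cell(row$perturbation)
    tl <- if (p$type == "distractor") apply_distractor(tl, p$freq_spec, 3L)
          else apply_deviant(tl, p$offset_st, 3L)
  }
  tl
}

#' Serialize a timeline to JSON
#'
#' @param timeline a `stimulus_timeline`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
timeline_to_json <- function(timeline, path = NULL) {
  obj <- list(total_ms = timeline$total_ms, df_st = timeline$df_st,
              base_freq_hz = timeline$base_freq_hz,
              perturbation = timeline$perturbation,
              events = timeline$events)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname timeline_to_json
#' @param json JSON string or file path to read back.
#' @export
timeline_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  ev <- as.data.frame(obj$events, stringsAsFactors = FALSE)
  ev$onset_ms <- as.integer(ev$onset_ms)
  ev$duration_ms <- as.integer(ev$duration_ms)
  new_timeline(ev, obj$total_ms, obj$df_st, obj$base_freq_hz,
               obj$perturbation)
}

#' Synthesize an audio waveform for a timeline
#'
#' Renders each tone as a pure sinusoid with linear on/off ramps; silent
#' intervals are exactly zero. Peak amplitude follows a digital full-scale
#' convention (65 dB maps to 0.5 full scale, 6 dB per factor 2); `level_db`
#' is not a calibrated SPL.
#'
#' @param timeline a `stimulus_timeline`.
#' @param sample_rate sampling rate in Hz (>= 8000).
#' @param ramp_ms linear ramp duration in ms (default 10).
#' @param level_db nominal presentation level (default 65).
#' @return numeric vector of samples in [-1, 1], length
#'   `total_ms * sample_rate / 1000`.
#' @export
synthesize_waveform <- function(timeline, sample_rate = 44100, ramp_ms = 10,
                                level_db = 65) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  if (sample_rate < 8000) stop("sample_rate must be >= 8000 Hz", call. = FALSE)
  if (any(2 * ramp_ms > timeline$events$duration_ms))
    stop("ramp_ms*2 exceeds a tone duration", call. = FALSE)
  n_total <- round(timeline$total_ms * sample_rate / 1000)
  buf <- numeric(n_total)
  amp <- 0.5 * 10^((level_db - 65) / 20)
  for (i in seq_len(nrow(timeline$events))) {
    ev <- timeline$events[i, ]
    n_tone <- round(ev$duration_ms * sample_rate / 1000)
    i0 <- round(ev$onset_ms * sample_rate / 1000)
    t <- (seq_len(n_tone) - 1) / sample_rate
    env <- tone_envelope(n_tone, round(ramp_ms * sample_rate / 1000))
    buf[i0 + seq_len(n_tone)] <- buf[i0 + seq_len(n_tone)] +
      amp * env * sin(2 * pi * ev$freq_hz * t)
  }
  attr(buf, "sample_rate") <- sample_rate
  buf
}

# linear on/off ramp envelope, 1.0 in the plateau
tone_envelope <- function(n, n_ramp) {
  env <- rep(1, n)
  if (n_ramp > 0) {
    ramp <- seq(0, 1, length.out = n_ramp)
    env[seq_len(n_ramp)] <- ramp
    env[n - n_ramp + seq_len(n_ramp)] <- rev(ramp)
  }
  env
}

#' Write samples to a WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit PCM and 32-bit IEEE float.
#'
#' @param samples numeric vector in [-1, 1] (e.g. from
#'   [synthesize_waveform()]).
#' @param path output file path.
#' @param sample_rate sampling rate in Hz; defaults to the samples'
#'   `sample_rate` attribute.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = attr(samples, "sample_rate"),
                      format = c("pcm16", "float32")) {
  format <- match.arg(format)
  if (is.null(sample_rate)) stop("sample_rate required", call. = FALSE)
  n <- length(samples)
  bits <- if (format == "pcm16") 16L else 32L
  block <- bits / 8L
  data_bytes <- n * block
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(if (format == "pcm16") 1L else 3L, 1L), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * block), con, size = 4, endian = "little")
  writeBin(c(as.integer(block), bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(as.integer(round(pmax(-1, pmin(1, samples)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}
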