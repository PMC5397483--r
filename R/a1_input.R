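# A1-like input stage: tonotopic pooling with fast onset adaptation,
# pause recovery, forward masking and novel-event handling.

#' A1 input-stage parameters
#'
#' Parameters of the input stage that converts a stimulus timeline into
#' per-unit drive, mimicking adapted responses in primary auditory cortex.
#'
#' Amplitude adaptation and the emergence of frequency (DF) dependence share
#' one fast timescale `tau_a1`; both recover toward their onset values
#' during silences exceeding the triplet grammar with timescale `tau_rec`.
#' The amplitude gain decays from `amp_onset_gain` to 1; the effective-DF
#' fraction rises from `df_onset_frac` to 1 (tones are represented
#' contracted toward the A/B midpoint by that fraction, which biases the
#' integration unit at stimulus onset).
#'
#' @param tau_a1 fast adaptation timescale, ms (default 500).
#' @param tau_rec recovery timescale during silence, ms (default 100).
#' @param tuning_width_st Gaussian tonotopic tuning width, semitones
#'   (peripheral units A and B).
#' @param ab_width_factor multiple of `tuning_width_st` used for the
#'   integration (AB) unit's pooling kernel (>= 1). The AB unit integrates
#'   over the region spanning both tones, so it pools a broader swath of
#'   the tonotopic axis than the peripheral units.
#' @param amp_onset_gain unadapted response amplitude relative to the
#'   adapted steady state (> 1).
#' @param df_onset_frac effective-DF fraction at onset, in (0, 1).
#' @param masking_factor attenuation of a non-triplet tone's response at the
#'   A location (forward masking by the preceding A tone), in [0, 1].
#' @param a_rate_masking amplitude factor on A-tone responses, in (0, 1].
#'   A tones recur at twice the B rate, so their responses are more
#'   forward-masked; that rate dependence is folded into this static
#'   constant.
#' @param boost_to_unadapted if `TRUE`, novel (distractor/deviant) events
#'   drive the competition stage at the unadapted amplitude.
#' @param gate_non_triplet_from_AB if `TRUE`, novel events are gated out of
#'   the integration (AB) unit's input (the differential-processing
#'   hypothesis); if `FALSE` they reach all units tonotopically.
#' @param input_scale overall drive scale applied to every pulse
#'   (dimensionless; sets where pulses sit relative to the competition
#'   stage's activation threshold).
#' @param adapting if `FALSE`, the input stage is static: amplitude gain 1
#'   and full DF dependence from the first triplet.
#' @return an `a1_params` list.
#' @export
a1_params <- function(tau_a1 = 500, tau_rec = 100, tuning_width_st = 3.5,
                      ab_width_factor = 2,
                      amp_onset_gain = 3, df_onset_frac = 0.03,
                      masking_factor = 0.5, a_rate_masking = 0.65,
                      boost_to_unadapted = TRUE,
                      gate_non_triplet_from_AB = TRUE, input_scale = 0.3,
                      adapting = TRUE) {
  if (tau_a1 <= 0 || tau_rec <= 0) stop("timescales must be > 0", call. = FALSE)
  if (tuning_width_st <= 0) stop("tuning_width_st must be > 0", call. = FALSE)
  if (ab_width_factor < 1) stop("ab_width_factor must be >= 1", call. = FALSE)
  if (amp_onset_gain < 1) stop("amp_onset_gain must be >= 1", call. = FALSE)
  if (df_onset_frac <= 0 || df_onset_frac > 1)
    stop("df_onset_frac must lie in (0, 1]", call. = FALSE)
  if (masking_factor < 0 || masking_factor > 1)
    stop("masking_factor must lie in [0, 1]", call. = FALSE)
  if (a_rate_masking <= 0 || a_rate_masking > 1)
    stop("a_rate_masking must lie in (0, 1]", call. = FALSE)
  structure(list(tau_a1 = tau_a1, tau_rec = tau_rec,
                 tuning_width_st = tuning_width_st,
                 ab_width_factor = ab_width_factor,
                 amp_onset_gain = amp_onset_gain,
                 df_onset_frac = df_onset_frac,
                 masking_factor = masking_factor,
                 a_rate_masking = a_rate_masking,
                 boost_to_unadapted = isTRUE(boost_to_unadapted),
                 gate_non_triplet_from_AB = isTRUE(gate_non_triplet_from_AB),
                 input_scale = input_scale, adapting = isTRUE(adapting)),
            class = "a1_params")
}

#' Adaptation state of the input stage
#'
#' @param params an [a1_params()] set; the default state is the unadapted
#'   (stimulus onset) state.
#' @param amp_state current amplitude gain, in `[1, amp_onset_gain]`.
#' @param df_state current effective-DF fraction, in `[df_onset_frac, 1]`.
#' @return an `adaptation_state` list.
#' @export
adaptation_state <- function(params, amp_state = params$amp_onset_gain,
                             df_state = params$df_onset_frac) {
  stopifnot(amp_state >= 1 - 1e-12, amp_state <= params$amp_onset_gain + 1e-12,
            df_state >= params$df_onset_frac - 1e-12, df_state <= 1 + 1e-12)
  structure(list(amp_state = amp_state, df_state = df_state),
            class = "adaptation_state")
}

#' Gaussian tonotopic pooling weight
#'
#' Weight with which a tone at one tonotopic location drives a unit pooling
#' A1 activity centered at another: `exp(-d^2 / (2 width^2))` with
#' `d = tone_freq_st - unit_center_st`.
#'
#' @param tone_freq_st tone location, semitones.
#' @param unit_center_st unit center, semitones.
#' @param width tuning width, semitones (> 0).
#' @return weight in (0, 1].
#' @export
tonotopic_weight <- function(tone_freq_st, unit_center_st, width) {
  if (any(width <= 0)) stop("width must be > 0", call. = FALSE)
  d <- tone_freq_st - unit_center_st
  exp(-d^2 / (2 * width^2))
}

#' Effective frequency difference under fast adaptation
#'
#' At stimulus onset the DF dependence of A1 responses is weak; it emerges
#' exponentially with timescale `tau_a1`. Returns the effective DF after
#' `t_since_onset` ms of uninterrupted stimulation.
#'
#' @param t_since_onset time since stimulation (re)started, ms.
#' @param df_nominal nominal DF, semitones (> 0).
#' @param params an [a1_params()] set.
#' @param state optional [adaptation_state()] at `t_since_onset = 0`
#'   (defaults to the unadapted onset state).
#' @return effective DF in semitones, rising from
#'   `df_onset_frac * df_nominal` toward `df_nominal`.
#' @export
effective_df <- function(t_since_onset, df_nominal, params, state = NULL) {
  if (df_nominal <= 0) stop("df_nominal must be > 0", call. = FALSE)
  f0 <- if (is.null(state)) params$df_onset_frac else state$df_state
  f <- 1 - (1 - f0) * exp(-t_since_onset / params$tau_a1)
  df_nominal * f
}

#' Recovery of adaptation during silence
#'
#' During a silent pause both adaptation variables relax exponentially back
#' toward their onset (unadapted) values with timescale `tau_rec`, so that
#' after a pause of a few `tau_rec` the input stage resembles stimulus
#' onset.
#'
#' @param state an [adaptation_state()].
#' @param silence_ms pause duration, ms (>= 0).
#' @param params an [a1_params()] set.
#' @return the recovered `adaptation_state`.
#' @export
recover_during_silence <- function(state, silence_ms, params) {
  if (silence_ms < 0) stop("silence_ms must be >= 0", call. = FALSE)
  k <- exp(-silence_ms / params$tau_rec)
  adaptation_state(params,
    amp_state = params$amp_onset_gain + (state$amp_state - params$amp_onset_gain) * k,
    df_state = params$df_onset_frac + (state$df_state - params$df_onset_frac) * k)
}

# Stimulation is "active" from each tone's onset until 100 ms past its
# offset (covering the triplet grammar's "_" silence); adaptation advances
# with tau_a1 while active and recovers with tau_rec otherwise, so only
# silences beyond the grammar (pauses) cause recovery.
adaptation_profile <- function(timeline, t, params) {
  n <- length(t)
  active <- logical(n)
  for (i in seq_len(nrow(timeline$events))) {
    ev <- timeline$events[i, ]
    active <- active | (t >= ev$onset_ms & t < ev$onset_ms + ev$duration_ms + 100)
  }
  amp <- numeric(n); f <- numeric(n)
  amp[1] <- params$amp_onset_gain; f[1] <- params$df_onset_frac
  dt <- t[2] - t[1]
  k_ad <- exp(-dt / params$tau_a1); k_rec <- exp(-dt / params$tau_rec)
  for (i in 2:n) {
    if (active[i - 1]) {
      amp[i] <- 1 + (amp[i - 1] - 1) * k_ad
      f[i] <- 1 - (1 - f[i - 1]) * k_ad
    } else {
      amp[i] <- params$amp_onset_gain + (amp[i - 1] - params$amp_onset_gain) * k_rec
      f[i] <- params$df_onset_frac + (f[i - 1] - params$df_onset_frac) * k_rec
    }
  }
  list(active = active, amp = amp, f = f)
}

unit_centers_st <- function(df_st) c(A = 0, AB = df_st / 2, B = df_st)

unit_widths_st <- function(params)
  params$tuning_width_st * c(A = 1, AB = params$ab_width_factor, B = 1)

#' Per-unit response to a novel (distractor or deviant) event
#'
#' Novel events that break the triplet pattern are treated specially: their
#' drive is boosted to the unadapted amplitude (if `boost_to_unadapted`),
#' their response at the A location is attenuated by `masking_factor`
#' (forward masking: the event closely follows an A-tone offset), and if
#' `gate_non_triplet_from_AB` is set their input to the integration (AB)
#' unit is gated out entirely.
#'
#' @param event one event row (fields `freq_hz`, `label`; label must be
#'   `"distractor"` or `"deviant"`).
#' @param state an [adaptation_state()] at the event's onset.
#' @param params an [a1_params()] set.
#' @param df_st nominal DF of the surrounding sequence, semitones.
#' @param base_freq_hz A-tone frequency, Hz.
#' @return named vector of pulse amplitudes for units A, AB, B.
#' @export
distractor_response <- function(event, state, params, df_st, base_freq_hz) {
  if (!event$label %in% c("distractor", "deviant"))
    stop("distractor_response applies only to distractor/deviant events",
         call. = FALSE)
  centers <- unit_centers_st(df_st)
  pos <- hz_to_st(event$freq_hz, base_freq_hz)
  amp <- if (params$boost_to_unadapted) params$amp_onset_gain else state$amp_state
  w <- tonotopic_weight(pos, centers, unit_widths_st(params))
  out <- params$input_scale * amp * w
  out["A"] <- out["A"] * params$masking_factor
  if (params$gate_non_triplet_from_AB) out["AB"] <- 0
  out
}

#' Compute the A1 input trace for a stimulus timeline
#'
#' Converts a `stimulus_timeline` into per-unit drive time series
#' `I_A(t), I_AB(t), I_B(t)` on a uniform grid. Each tone contributes a
#' rectangular pulse for its duration, scaled by the current amplitude gain
#' and by the Gaussian tonotopic weight between the tone's effective
#' location and the unit's center (A at 0 st, B at DF st, AB at their
#' midpoint). Under adaptation, tone locations are contracted toward the
#' midpoint by the effective-DF fraction, and the amplitude gain decays from
#' its onset value; both recover during pauses. Distractor and deviant
#' events follow [distractor_response()].
#'
#' @param timeline a `stimulus_timeline`.
#' @param params an [a1_params()] set.
#' @param dt grid step in ms; must divide the ms event grid.
#' @return an `a1_input_trace`: time grid `t` (ms), drive matrix `I`
#'   (columns A, AB, B), the adaptation profile, and a per-event provenance
#'   table of pulse amplitudes.
#' @export
compute_input_trace <- function(timeline, params, dt = 5) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  if (dt <= 0 || min(100 %% dt, dt - 100 %% dt) > 1e-6)
    stop("dt must be a positive step dividing the 100 ms tone grid", call. = FALSE)
  t <- seq(0, timeline$total_ms, by = dt)
  n <- length(t)
  I <- matrix(0, n, 3, dimnames = list(NULL, c("A", "AB", "B")))
  if (nrow(timeline$events) == 0) {
    return(structure(list(t = t, I = I, dt = dt, timeline = timeline,
                          params = params, provenance = NULL),
                     class = "a1_input_trace"))
  }
  prof <- if (params$adapting) adaptation_profile(timeline, t, params)
          else list(amp = rep(1, n), f = rep(1, n))
  centers <- unit_centers_st(timeline$df_st)
  widths <- unit_widths_st(params)
  mid <- timeline$df_st / 2
  prov <- vector("list", nrow(timeline$events))
  for (i in seq_len(nrow(timeline$events))) {
    ev <- timeline$events[i, ]
    on <- which(t >= ev$onset_ms & t < ev$onset_ms + ev$duration_ms)
    if (length(on) == 0) next
    pos <- hz_to_st(ev$freq_hz, timeline$base_freq_hz)
    if (ev$label %in% c("A", "B")) {
      pos_eff <- mid + prof$f[on] * (pos - mid)
      amp <- prof$amp[on] * if (ev$label == "A") params$a_rate_masking else 1
      contrib <- params$input_scale * amp *
        vapply(seq_along(centers), function(k)
          tonotopic_weight(pos_eff, centers[k], widths[k]),
          numeric(length(on)))
      contrib <- matrix(contrib, nrow = length(on))
    } else {
      st0 <- adaptation_state(params, amp_state = prof$amp[on[1]],
                              df_state = prof$f[on[1]])
      pulse <- distractor_response(ev, st0, params, timeline$df_st,
                                   timeline$base_freq_hz)
      contrib <- matrix(pulse, length(on), 3, byrow = TRUE)
    }
    I[on, ] <- I[on, ] + contrib
    prov[[i]] <- data.frame(event = i, label = ev$label, onset_ms = ev$onset_ms,
                            freq_hz = ev$freq_hz, pos_st = pos,
                            amp_A = contrib[1, 1], amp_AB = contrib[1, 2],
                            amp_B = contrib[1, 3])
  }
  structure(list(t = t, I = I, dt = dt, timeline = timeline, params = params,
                 provenance = do.call(rbind, prov)),
            class = "a1_input_trace")
}

#' @export
print.a1_input_trace <- function(x, ...) {
  cat(sprintf("<a1_input_trace> %d samples at dt = %g ms (%g ms total), %s input\n",
              length(x$t), x$dt, max(x$t),
              if (x$params$adapting) "adapting" else "static"))
  invisible(x)
}

#' Write an input trace to a columnar text file
#'
#' @param trace an `a1_input_trace`.
#' @param path output path (tab-separated columns: time_ms, I_A, I_AB, I_B).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_ms = trace$t, I_A = trace$I[, "A"],
                   I_AB = trace$I[, "AB"], I_B = trace$I[, "B"])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
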