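# Percept readout, build-up functions, difference scores, sweeps and the
# calibration harness.

#' Classify time bins as integrated or segregated
#'
#' Applies the percept readout rule per time bin: a bin is integrated when
#' the AB unit's activity exceeds (or ties) the summed activity of the A
#' and B units, segregated otherwise. By default activities are
#' bin-averaged rates; `mode = "sample"` instead compares sample-by-sample
#' and takes the bin's majority.
#'
#' @param x a `stream_ensemble` or `network_trajectory`.
#' @param bin_ms bin width in ms (default 400, one triplet); must divide
#'   the trajectory duration.
#' @param mode `"bin_average"` (default) or `"sample"`.
#' @return logical matrix `[n_trials, n_bins]`, `TRUE` = segregated, with
#'   attribute `bin_centers` (ms).
#' @export
classify_bins <- function(x, bin_ms = 400, mode = c("bin_average", "sample")) {
  mode <- match.arg(mode)
  if (inherits(x, "network_trajectory")) {
    r <- array(x$r, dim = c(nrow(x$r), 1, 3))
    t <- x$t
  } else if (inherits(x, "stream_ensemble")) {
    r <- x$r; t <- x$t
  } else stop("x must be a stream_ensemble or network_trajectory", call. = FALSE)
  if (length(t) < 2) stop("empty trajectory", call. = FALSE)
  total <- max(t)
  n_bins <- floor(total / bin_ms + 1e-9)
  if (n_bins < 1)
    stop("bin_ms exceeds the trajectory duration", call. = FALSE)
  # a trailing partial bin (e.g. after a pause shifts the grid) is dropped;
  # bins continue across silent intervals
  bin_of <- floor(t / bin_ms + 1e-9) + 1L
  bin_of[t >= n_bins * bin_ms - 1e-9] <- n_bins   # endpoint joins the last bin
  keep <- t <= n_bins * bin_ms + 1e-9
  t <- t[keep]; bin_of <- bin_of[keep]
  r <- r[keep, , , drop = FALSE]
  n_trials <- dim(r)[2]
  seg <- matrix(NA, n_trials, n_bins)
  excess <- r[, , 2] - (r[, , 1] + r[, , 3])      # AB minus (A + B), [time, trial]
  excess <- matrix(excess, nrow = length(t))
  for (b in seq_len(n_bins)) {
    rows <- bin_of == b
    if (mode == "bin_average") {
      seg[, b] <- colMeans(excess[rows, , drop = FALSE]) < 0
    } else {
      seg[, b] <- colMeans(excess[rows, , drop = FALSE] < 0) > 0.5
    }
  }
  attr(seg, "bin_centers") <- (seq_len(n_bins) - 0.5) * bin_ms
  seg
}

#' Proportion segregated in an arbitrary time window
#'
#' Applies the percept readout (bin-averaged AB activity vs summed A and B
#' activity) to one window `[t0, t1]` of an ensemble. Used to evaluate
#' difference scores at the final test triplet when a pause has shifted the
#' triplet grid off the bin grid.
#'
#' @param ensemble a `stream_ensemble`.
#' @param t0,t1 window bounds in ms (defaults: the final 400 ms).
#' @return proportion of trials segregated in the window, with attribute
#'   `sem`.
#' @export
prop_seg_window <- function(ensemble, t0 = max(ensemble$t) - 400,
                            t1 = max(ensemble$t)) {
  rows <- ensemble$t >= t0 - 1e-9 & ensemble$t <= t1 + 1e-9
  if (!any(rows)) stop("window contains no samples", call. = FALSE)
  excess <- ensemble$r[rows, , 2] - (ensemble$r[rows, , 1] + ensemble$r[rows, , 3])
  excess <- matrix(excess, nrow = sum(rows))
  seg <- colMeans(excess) < 0
  p <- mean(seg)
  structure(p, sem = sqrt(p * (1 - p) / length(seg)))
}

#' Build-up function of an ensemble
#'
#' The time-binned, trial-averaged proportion of segregated percepts, the
#' standard summary of how stream segregation develops after stimulus
#' onset.
#'
#' @param ensemble a `stream_ensemble` (or a list of `network_trajectory`
#'   objects on a common grid).
#' @param bin_ms bin width in ms (default 400).
#' @param meta optional named list of condition metadata to carry along.
#' @return a `build_up_function` data.frame: `bin_center` (ms),
#'   `prop_seg`, `sem` (binomial, `sqrt(p(1-p)/n)`), `n_trials`.
#' @export
build_up <- function(ensemble, bin_ms = 400, meta = list()) {
  if (is.list(ensemble) && !inherits(ensemble, "stream_ensemble") &&
      all(vapply(ensemble, inherits, logical(1), "network_trajectory"))) {
    seg <- do.call(rbind, lapply(ensemble, classify_bins, bin_ms = bin_ms))
    attr(seg, "bin_centers") <- attr(classify_bins(ensemble[[1]], bin_ms), "bin_centers")
  } else {
    seg <- classify_bins(ensemble, bin_ms = bin_ms)
  }
  p <- colMeans(seg)
  n <- nrow(seg)
  out <- data.frame(bin_center = attr(seg, "bin_centers"), prop_seg = p,
                    sem = sqrt(p * (1 - p) / n), n_trials = n)
  attr(out, "meta") <- meta
  attr(out, "bin_ms") <- bin_ms
  class(out) <- c("build_up_function", "data.frame")
  out
}

#' Snapshot a build-up function at given triplets
#'
#' @param buf a `build_up_function` with one bin per triplet.
#' @param triplet_indices triplet numbers (1-based bins).
#' @return named numeric vector of proportions segregated.
#' @export
snapshot <- function(buf, triplet_indices) {
  if (any(triplet_indices < 1 | triplet_indices > nrow(buf)))
    stop(sprintf("triplet indices must lie in [1, %d]", nrow(buf)), call. = FALSE)
  stats::setNames(buf$prop_seg[triplet_indices],
                  paste0("triplet", triplet_indices))
}

#' Difference score between test and control build-up
#'
#' `delta = p_test - p_control` at one bin (by default the final test bin,
#' mirroring reports of the last triplet). Positive deltas indicate
#' promotion of segregation; negative deltas a reset toward integration.
#'
#' @param test,control `build_up_function` objects.
#' @param at_bin bin index in the test function (default: last).
#' @return the delta (single numeric), with attribute `sem` (combined
#'   binomial sem of the two proportions).
#' @export
difference_score <- function(test, control, at_bin = nrow(test)) {
  if (at_bin < 1 || at_bin > nrow(test) || at_bin > nrow(control))
    stop("at_bin outside the common bin range", call. = FALSE)
  if (abs(test$bin_center[at_bin] - control$bin_center[at_bin]) > 1e-9)
    stop("test and control bin grids disagree at the evaluation bin",
         call. = FALSE)
  delta <- test$prop_seg[at_bin] - control$prop_seg[at_bin]
  attr(delta, "sem") <- sqrt(test$sem[at_bin]^2 + control$sem[at_bin]^2)
  delta
}

#' Simulate one stimulus condition and summarize its build-up
#'
#' Computes the input trace for a timeline, runs a frozen-noise ensemble
#' and returns the build-up function. Static-input conditions describe the
#' post-build-up alternation regime, so by default they are observed after
#' a 2.4 s burn-in (prepended triplets, discarded before binning).
#'
#' @param timeline a `stimulus_timeline`.
#' @param a1,net parameter sets ([a1_params()], [network_params()]).
#' @param n_trials ensemble size.
#' @param master_seed frozen-noise master seed.
#' @param bin_ms readout bin width, ms.
#' @param burn_in_ms discarded lead-in (default 0 for adapting input,
#'   2400 ms for static input; only available for unperturbed timelines).
#' @return a `build_up_function`.
#' @export
condition_buildup <- function(timeline, a1, net, n_trials, master_seed,
                              bin_ms = 400, burn_in_ms = if (a1$adapting) 0 else 2400) {
  if (burn_in_ms > 0) {
    stopifnot(timeline$perturbation$type == "none")
    n_burn <- ceiling(burn_in_ms / 400)
    n_tot <- n_triplets_of(timeline) + n_burn
    timeline <- make_triplet_sequence(n_tot, timeline$df_st, timeline$base_freq_hz)
    burn_in_ms <- n_burn * 400
  }
  inp <- compute_input_trace(timeline, a1, dt = net$dt)
  ens <- run_ensemble(inp, net, n_trials = n_trials, master_seed = master_seed,
                      discard_ms = burn_in_ms)
  build_up(ens, bin_ms = bin_ms,
           meta = list(df_st = timeline$df_st,
                       perturbation = timeline$perturbation$type))
}

#' Sweep distractor frequency against its effect on segregation
#'
#' For each DF and each distractor frequency specification, simulates a
#' six-triplet sequence with the distractor after the third triplet and a
#' matched no-distractor control under frozen noise, and reports the
#' difference in proportion segregated at the final triplet.
#'
#' @param freq_specs character vector of specs (see [resolve_freq_spec()]).
#' @param df_list DF values in semitones.
#' @param hypothesis `"gated"` (novel events excluded from the AB unit) or
#'   `"ungated"`.
#' @param n_trials ensemble size per condition.
#' @param master_seed frozen-noise master seed.
#' @param a1,net parameter sets (defaults: [a1_params()],
#'   [network_params()]).
#' @param n_triplets sequence length (default 6).
#' @param base_freq_hz A-tone frequency.
#' @return a `sweep_result` data.frame: df_st, freq_spec, delta, sem.
#' @export
distractor_sweep <- function(freq_specs, df_list = c(4, 7, 10),
                             hypothesis = c("gated", "ungated"),
                             n_trials = 500, master_seed = 1,
                             a1 = a1_params(), net = network_params(),
                             n_triplets = 6, base_freq_hz = 420) {
  hypothesis <- match.arg(hypothesis)
  a1$gate_non_triplet_from_AB <- hypothesis == "gated"
  rows <- list()
  for (df in df_list) {
    ctrl_tl <- make_triplet_sequence(n_triplets, df, base_freq_hz)
    ctrl <- condition_buildup(ctrl_tl, a1, net, n_trials, master_seed)
    for (spec in freq_specs) {
      tl <- apply_distractor(ctrl_tl, spec, 3L)
      test <- condition_buildup(tl, a1, net, n_trials, master_seed)
      d <- difference_score(test, ctrl)
      rows[[length(rows) + 1L]] <- data.frame(
        df_st = df, freq_spec = spec, hypothesis = hypothesis,
        delta = as.numeric(d), sem = attr(d, "sem"))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' First switch to segregation in a trajectory
#'
#' Time (ms) of the first triplet bin classified segregated, or `NA` if the
#' trial never segregates.
#'
#' @param traj a `network_trajectory`.
#' @param bin_ms bin width in ms.
#' @return first-switch time in ms (bin end), or `NA`.
#' @export
first_switch_time <- function(traj, bin_ms = 400) {
  seg <- classify_bins(traj, bin_ms = bin_ms)
  idx <- which(seg[1, ])[1]
  if (is.na(idx)) return(NA_real_)
  idx * bin_ms
}

#' Calibration harness for under-constrained parameters
#'
#' Scans candidate parameter sets and evaluates each against a list of
#' qualitative criteria (predicates on the simulated model), returning the
#' first fully passing set together with a per-criterion report. With an
#' empty criteria list the defaults are returned unchanged.
#'
#' @param candidates data.frame of parameter overrides, one candidate per
#'   row; column names may address A1 fields (`a1.` prefix) or network
#'   fields (`net.` prefix).
#' @param criteria named list of functions `function(a1, net) -> logical`.
#' @param a1,net baseline parameter sets the overrides are applied to.
#' @return a `calibration_report`: `passed` (logical), `chosen` (a1 + net
#'   lists), and a data.frame `report` of per-candidate, per-criterion
#'   outcomes.
#' @export
calibrate <- function(candidates = NULL, criteria = list(),
                      a1 = a1_params(), net = network_params()) {
  if (length(criteria) == 0) {
    return(structure(list(passed = TRUE, chosen = list(a1 = a1, net = net),
                          report = data.frame()),
                     class = "calibration_report"))
  }
  if (is.null(candidates) || nrow(candidates) == 0)
    candidates <- data.frame(.baseline = 0)
  rows <- list()
  best <- NULL; best_n <- -1L
  for (ci in seq_len(nrow(candidates))) {
    a1_c <- a1; net_c <- net
    for (nm in setdiff(names(candidates), ".baseline")) {
      val <- candidates[[nm]][ci]
      if (startsWith(nm, "a1.")) a1_c[[sub("^a1\\.", "", nm)]] <- val
      else if (startsWith(nm, "net.")) net_c[[sub("^net\\.", "", nm)]] <- val
      else stop(sprintf("candidate column '%s' needs an a1. or net. prefix", nm),
                call. = FALSE)
    }
    res <- vapply(criteria, function(f) isTRUE(f(a1_c, net_c)), logical(1))
    rows[[ci]] <- data.frame(candidate = ci, criterion = names(criteria),
                             passed = unname(res))
    if (sum(res) > best_n) { best_n <- sum(res); best <- list(a1 = a1_c, net = net_c) }
    if (all(res)) {
      return(structure(list(passed = TRUE, chosen = list(a1 = a1_c, net = net_c),
                            report = do.call(rbind, rows)),
                       class = "calibration_report"))
    }
  }
  structure(list(passed = FALSE, chosen = best, report = do.call(rbind, rows)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %s\n",
              if (x$passed) "all criteria passed" else "NO fully passing candidate"))
  if (nrow(x$report)) print(x$report)
  invisible(x)
}

#' Write a build-up function (or list of them) to CSV
#'
#' @param bufs a `build_up_function` or named list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_buildup_csv <- function(bufs, path) {
  if (inherits(bufs, "build_up_function")) bufs <- list(condition = bufs)
  rows <- lapply(names(bufs), function(nm) {
    b <- bufs[[nm]]
    meta <- attr(b, "meta")
    cbind(condition = nm,
          df_st = if (!is.null(meta$df_st)) meta$df_st else NA,
          as.data.frame(b))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
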