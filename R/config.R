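# Configuration schema, experiment runner, provenance.

#' Default run configuration
#'
#' Bundles every model constant and experiment setting into one nested
#' list: the competition-stage constants (rate timescale 10 ms, NMDA-like
#' excitation 70 ms at strength 0.65, global inhibition 0.3, adaptation
#' strength 0.045 at 1.4 s), the input-stage constants (fast adaptation
#' 500 ms, recovery 100 ms), the Euler-Maruyama step (half the rate
#' timescale) and the 500-trial ensemble default.
#'
#' @return a `run_config` list with elements `network`, `a1`,
#'   `experiment`, `n_trials`, `master_seed`, `bin_ms`, `df_list`,
#'   `base_freq_hz`, `n_triplets`, `cells`, `sweep_specs`, `figures`,
#'   `out_dir`.
#' @export
default_config <- function() {
  structure(list(
    network = unclass(network_params()),
    a1 = unclass(a1_params()),
    experiment = "buildup",
    n_trials = 500L,
    master_seed = 1L,
    bin_ms = 400,
    df_list = c(4, 7, 10),
    base_freq_hz = 420,
    n_triplets = 10L,
    cells = c("disB+2", "dev+2"),
    sweep_specs = c("A-2", "A", "(A+B)/2", "B", "B+2", "B+4", "B+8", "B+15"),
    figures = FALSE,
    out_dir = "."
  ), class = "run_config")
}

check_unknown_keys <- function(user, ref, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(ref))
      stop(sprintf("unknown config key '%s%s'", path, nm), call. = FALSE)
    if (is.list(user[[nm]]) && is.list(ref[[nm]]))
      check_unknown_keys(user[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Validate a run configuration
#'
#' Re-runs the parameter constructors on the stored values (so every
#' constraint they enforce applies, notably `beta_e > beta_i`) and checks
#' the grid constraint that the step divides the 100 ms tone duration.
#'
#' @param config a `run_config` list.
#' @return the config, invisibly; errors name the offending key.
#' @export
validate_config <- function(config) {
  net <- try(do.call(network_params, config$network), silent = TRUE)
  if (inherits(net, "try-error"))
    stop("config key 'network': ", attr(net, "condition")$message, call. = FALSE)
  a1 <- try(do.call(a1_params, config$a1), silent = TRUE)
  if (inherits(a1, "try-error"))
    stop("config key 'a1': ", attr(a1, "condition")$message, call. = FALSE)
  if (abs(100 %% config$network$dt) > 1e-9)
    stop("config key 'network.dt': must divide the 100 ms tone duration",
         call. = FALSE)
  if (config$n_trials < 1) stop("config key 'n_trials': must be >= 1", call. = FALSE)
  invisible(config)
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys are filled from
#' [default_config()]; the resolved configuration is echoed to the log.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`); an empty file yields
#'   the full default configuration.
#' @param quiet suppress the resolved-config echo.
#' @return a validated `run_config`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(user)) user <- list()
  base <- default_config()
  check_unknown_keys(user, base)
  config <- merge_config(base, user)
  class(config) <- "run_config"
  validate_config(config)
  if (!quiet)
    message("resolved config: ",
            jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
  config
}

config_params <- function(config) {
  list(net = do.call(network_params, config$network),
       a1 = do.call(a1_params, config$a1))
}

#' Run a configured experiment
#'
#' Executes one of the packaged experiments and writes its artifact bundle
#' (CSV tables, optional figures, and a provenance JSON) to
#' `config$out_dir`. All randomness derives from `config$master_seed`, so
#' repeated runs are byte-identical.
#'
#' Experiments:
#' \describe{
#'   \item{`buildup`}{build-up functions for each DF under static and
#'     adapting input (10 triplets).}
#'   \item{`pause`}{the pause paradigm: 3/7/10-triplet controls plus
#'     7 + pause(300/600 ms) + 3 conditions, with difference scores at the
#'     final triplet.}
#'   \item{`perturbation`}{3/6-triplet controls plus the configured
#'     distractor/deviant cells, with difference scores.}
#'   \item{`sweep`}{distractor-frequency sweep over
#'     `config$sweep_specs`.}
#' }
#'
#' @param config a `run_config` (see [default_config()], [load_config()]).
#' @return invisibly, a list of written file paths plus the in-memory
#'   results.
#' @export
run_experiment <- function(config = default_config()) {
  validate_config(config)
  p <- config_params(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(files = character(0))
  seed <- config$master_seed
  nt <- config$n_trials

  if (config$experiment == "buildup") {
    bufs <- list()
    for (df in config$df_list) {
      for (mode in c("static", "adapting")) {
        a1 <- p$a1; a1$adapting <- mode == "adapting"
        bufs[[sprintf("df%g_%s", df, mode)]] <-
          condition_buildup(make_triplet_sequence(config$n_triplets, df,
                                                  config$base_freq_hz),
                            a1, p$net, nt, seed, config$bin_ms)
      }
    }
    f <- file.path(config$out_dir, "buildup.csv")
    write_buildup_csv(bufs, f)
    out$files <- f; out$buildup <- bufs
  } else if (config$experiment == "pause") {
    res <- run_pause_conditions(p$a1, p$net, nt, seed, config$df_list,
                                config$base_freq_hz, config$bin_ms)
    f1 <- file.path(config$out_dir, "pause_buildup.csv")
    write_buildup_csv(res$bufs, f1)
    f2 <- file.path(config$out_dir, "pause_deltas.csv")
    utils::write.csv(res$deltas, f2, row.names = FALSE)
    out$files <- c(f1, f2); out$pause <- res
  } else if (config$experiment == "perturbation") {
    res <- run_perturbation_conditions(p$a1, p$net, nt, seed, config$df_list,
                                       config$cells, config$base_freq_hz,
                                       config$bin_ms)
    f1 <- file.path(config$out_dir, "perturbation_buildup.csv")
    write_buildup_csv(res$bufs, f1)
    f2 <- file.path(config$out_dir, "perturbation_deltas.csv")
    utils::write.csv(res$deltas, f2, row.names = FALSE)
    out$files <- c(f1, f2); out$perturbation <- res
  } else if (config$experiment == "sweep") {
    sw <- distractor_sweep(config$sweep_specs, config$df_list,
                           hypothesis = if (p$a1$gate_non_triplet_from_AB)
                             "gated" else "ungated",
                           n_trials = nt, master_seed = seed,
                           a1 = p$a1, net = p$net,
                           base_freq_hz = config$base_freq_hz)
    f <- file.path(config$out_dir, "sweep.csv")
    utils::write.csv(sw, f, row.names = FALSE)
    out$files <- f; out$sweep <- sw
  } else {
    stop(sprintf("unknown experiment '%s'", config$experiment), call. = FALSE)
  }

  if (isTRUE(config$figures)) {
    fig <- try(write_experiment_figure(out, config), silent = TRUE)
    if (!inherits(fig, "try-error") && !is.null(fig))
      out$files <- c(out$files, fig)
  }
  out$files <- c(out$files, write_provenance(config))
  invisible(out)
}

#' Pause-paradigm conditions
#'
#' Simulates, for each DF, the 3/7/10-triplet controls and the
#' 7 + pause + 3 test conditions under frozen noise, and the
#' pause-vs-10-triplet-control difference scores at the final triplet.
#'
#' @param a1,net parameter sets.
#' @param n_trials ensemble size.
#' @param master_seed frozen-noise master seed.
#' @param df_list DF values (st).
#' @param base_freq_hz A-tone frequency.
#' @param bin_ms readout bin (ms).
#' @return list with `bufs` (named build-up functions) and `deltas`
#'   (data.frame df_st, condition, delta, sem).
#' @export
run_pause_conditions <- function(a1, net, n_trials, master_seed,
                                 df_list = c(4, 7, 10), base_freq_hz = 420,
                                 bin_ms = 400) {
  bufs <- list(); deltas <- list()
  for (df in df_list) {
    tl10 <- make_triplet_sequence(10, df, base_freq_hz)
    inp10 <- compute_input_trace(tl10, a1, dt = net$dt)
    ens10 <- run_ensemble(inp10, net, n_trials = n_trials, master_seed = master_seed)
    p_ctl <- prop_seg_window(ens10)
    bufs[[sprintf("df%g_10T", df)]] <-
      build_up(ens10, bin_ms, meta = list(df_st = df, perturbation = "none"))
    bufs[[sprintf("df%g_3T", df)]] <-
      condition_buildup(make_triplet_sequence(3, df, base_freq_hz),
                        a1, net, n_trials, master_seed, bin_ms)
    bufs[[sprintf("df%g_7T", df)]] <-
      condition_buildup(make_triplet_sequence(7, df, base_freq_hz),
                        a1, net, n_trials, master_seed, bin_ms)
    for (pms in c(300, 600)) {
      tl <- apply_pause(tl10, pms, 7L)
      inp <- compute_input_trace(tl, a1, dt = net$dt)
      ens <- run_ensemble(inp, net, n_trials = n_trials, master_seed = master_seed)
      bufs[[sprintf("df%g_pause%d", df, pms)]] <-
        build_up(ens, bin_ms, meta = list(df_st = df,
                                          perturbation = sprintf("pause%d", pms)))
      # readout at the final test triplet, whose window the pause shifted
      p_test <- prop_seg_window(ens)
      deltas[[length(deltas) + 1L]] <- data.frame(
        df_st = df, condition = sprintf("pause%d", pms),
        delta = as.numeric(p_test) - as.numeric(p_ctl),
        sem = sqrt(attr(p_test, "sem")^2 + attr(p_ctl, "sem")^2))
    }
  }
  list(bufs = bufs, deltas = do.call(rbind, deltas))
}

#' Perturbation-paradigm conditions
#'
#' Simulates, for each DF, the 3/6-triplet controls and the requested
#' distractor/deviant cells (perturbation tied to the third triplet of a
#' six-triplet sequence) under frozen noise, with difference scores
#' against the 6-triplet control at the final triplet.
#'
#' @inheritParams run_pause_conditions
#' @param cells perturbation cell names (see
#'   [perturbation_experiment_design()]).
#' @return list with `bufs` and `deltas` as in
#'   [run_pause_conditions()].
#' @export
run_perturbation_conditions <- function(a1, net, n_trials, master_seed,
                                        df_list = c(4, 7, 10),
                                        cells = c("disB+2", "dev+2"),
                                        base_freq_hz = 420, bin_ms = 400) {
  bufs <- list(); deltas <- list()
  for (df in df_list) {
    base_tl <- make_triplet_sequence(6, df, base_freq_hz)
    ctl <- condition_buildup(base_tl, a1, net, n_trials, master_seed, bin_ms)
    bufs[[sprintf("df%g_6T", df)]] <- ctl
    bufs[[sprintf("df%g_3T", df)]] <-
      condition_buildup(make_triplet_sequence(3, df, base_freq_hz),
                        a1, net, n_trials, master_seed, bin_ms)
    for (cell in cells) {
      pc <- parse_perturbation_cell(cell)
      tl <- if (pc$type == "distractor") apply_distractor(base_tl, pc$freq_spec, 3L)
            else apply_deviant(base_tl, pc$offset_st, 3L)
      buf <- condition_buildup(tl, a1, net, n_trials, master_seed, bin_ms)
      bufs[[sprintf("df%g_%s", df, cell)]] <- buf
      d <- difference_score(buf, ctl)
      deltas[[length(deltas) + 1L]] <- data.frame(
        df_st = df, condition = cell, delta = as.numeric(d), sem = attr(d, "sem"))
    }
  }
  list(bufs = bufs, deltas = do.call(rbind, deltas))
}

write_provenance <- function(config) {
  cfg_path <- file.path(config$out_dir, "provenance.json")
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  prov <- list(
    package = "streamseg",
    version = as.character(utils::packageVersion("streamseg")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    master_seed = config$master_seed,
    config_hash = unname(tools::md5sum(tmp)),
    config = unclass(config))
  unlink(tmp)
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             cfg_path)
  cfg_path
}

# best-effort figure output; requires ggplot2
write_experiment_figure <- function(out, config) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(NULL)
  bufs <- out$buildup %||% out$pause$bufs %||% out$perturbation$bufs
  if (is.null(bufs)) return(NULL)
  df <- do.call(rbind, lapply(names(bufs), function(nm)
    cbind(condition = nm, as.data.frame(bufs[[nm]]))))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center / 1000,
                                         y = .data$prop_seg,
                                         colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "proportion segregated") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  path <- file.path(config$out_dir, sprintf("%s.png", config$experiment))
  ggplot2::ggsave(path, gg, width = 7, height = 4, dpi = 150)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
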