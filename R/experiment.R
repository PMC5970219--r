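#' Validated experiment configuration
#'
#' Bundles a full simulation experiment: model parameters, sound-exposure
#' condition, population size, master seed, snapshot schedule, and output
#' directory. Unknown keys are rejected; parameter values are validated by
#' [model_params()].
#'
#' @param params named list of [model_params()] overrides (empty for the
#'   published defaults).
#' @param condition sound-exposure condition, see [run_sound_phase()].
#' @param n_cells population size.
#' @param master_seed integer master seed.
#' @param snapshot_steps snapshot schedule; \code{NULL} for
#'   [default_snapshots()].
#' @param out_dir output directory for [run_experiment()].
#' @param sweep_at snapshot step(s) at which to measure sweep selectivity;
#'   defaults to the final snapshot.
#' @return an object of class \code{experiment_config}.
#' @export
experiment_config <- function(params = list(), condition = "single_channel",
                              n_cells = 100, master_seed = 1,
                              snapshot_steps = NULL, out_dir = ".",
                              sweep_at = NULL) {
  stopifnot(is.list(params))
  bad <- setdiff(names(params), names(formals(model_params)))
  if (length(bad))
    stop("unknown model parameter key(s): ", paste(bad, collapse = ", "))
  mp <- do.call(model_params, params)
  condition <- match.arg(condition, sound_conditions)
  if (is.null(snapshot_steps)) snapshot_steps <- default_snapshots(mp)
  structure(list(params = mp, condition = condition,
                 n_cells = as.integer(n_cells),
                 master_seed = as.integer(master_seed),
                 snapshot_steps = sort(unique(as.integer(snapshot_steps))),
                 out_dir = out_dir,
                 sweep_at = sweep_at),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' The YAML file may contain any [experiment_config()] field; the
#' \code{params} block holds [model_params()] overrides. Unknown keys at
#' either level are rejected.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
load_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(experiment_config)))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(experiment_config, raw)
}

#' Run a configured population experiment and persist its outputs
#'
#' Simulates the population, probes receptive fields at every snapshot
#' (and sweep selectivity at the final snapshot), and writes a per-cell
#' summary CSV plus a divergence-statistics JSON into the configured
#' output directory.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the population \code{records}, the
#'   \code{summary} table, and the written file paths.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  p <- config$params
  if (!quiet)
    message("simulating ", config$n_cells, " cells (", config$condition,
            ", master seed ", config$master_seed, ")")
  records <- run_population(config$n_cells, p, config$condition,
                            config$master_seed, config$snapshot_steps)
  sweep_at <- if (is.null(config$sweep_at))
    max(config$snapshot_steps) else config$sweep_at
  tabs <- lapply(config$snapshot_steps, function(t)
    cbind(t = t, population_fra_table(records, t, sweep = t %in% sweep_at)))
  summary <- do.call(rbind, lapply(tabs, function(x) {
    x[setdiff(c("t", "cell", "on_cf", "off_cf", "cf_diff_oct", "rate_up",
                "rate_down", "selectivity"), names(x))] <- NA
    x[c("t", "cell", "on_cf", "off_cf", "cf_diff_oct", "rate_up",
        "rate_down", "selectivity")]
  }))
  stats <- population_divergence_stats(records, p$t_young,
                                       min(p$t_adult, max(config$snapshot_steps)))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(config$out_dir,
                        paste0("population_", config$condition, ".csv"))
  json_path <- file.path(config$out_dir,
                         paste0("stats_", config$condition, ".json"))
  utils::write.csv(summary, csv_path, row.names = FALSE)
  jsonlite::write_json(stats, json_path, auto_unbox = TRUE, digits = NA)
  if (!quiet) message("wrote ", csv_path, " and ", json_path)
  invisible(list(records = records, summary = summary, stats = stats,
                 files = c(csv_path, json_path)))
}

#' Figure-level population statistics
#'
#' Recomputes the headline population statistics of the model: the
#' developmental divergence of ON/OFF CFs (\code{"divergence"}), the
#' comparison of the independent-sequence condition against the
#' alternating condition (\code{"independence"}), and the CF-difference /
#' sweep-selectivity correlations with and without inhibition
#' (\code{"sweep_correlation"}).
#'
#' @param analysis one of \code{"divergence"}, \code{"independence"},
#'   \code{"sweep_correlation"}.
#' @param params a [model_params()] object.
#' @param n_cells population size (published simulations use 100).
#' @param master_seed integer master seed.
#' @return named list of statistics (see details of each branch).
#' @export
reproduce_stats <- function(analysis = c("divergence", "independence",
                                         "sweep_correlation"),
                            params = model_params(), n_cells = 100,
                            master_seed = 1) {
  analysis <- match.arg(analysis)
  snaps <- default_snapshots(params)
  pop <- function(condition, seed_offset = 0)
    run_population(n_cells, params, condition,
                   master_seed + seed_offset, snaps)
  if (analysis == "divergence") {
    records <- pop("single_channel")
    ho_young <- population_divergence_stats(records, 0, params$t_young)
    young_adult <- population_divergence_stats(records, params$t_young,
                                               params$t_adult)
    list(mean_hearing_onset = ho_young$mean_a,
         mean_young = ho_young$mean_b,
         mean_adult = young_adult$mean_b,
         ks_young_adult = young_adult[c("ks_statistic", "p_value")])
  } else if (analysis == "independence") {
    alt <- population_divergence_stats(pop("single_channel"),
                                       params$t_adult, params$t_adult)
    ind <- population_divergence_stats(pop("independent_on_off", 1),
                                       params$t_adult, params$t_adult)
    list(mean_alternating = alt$mean_a, mean_independent = ind$mean_a)
  } else {
    exin <- cfdiff_selectivity_correlation(pop("single_channel"),
                                           t = params$t_adult)
    exonly <- cfdiff_selectivity_correlation(pop("excitation_only"),
                                             t = params$t_adult)
    list(ex_in = exin[c("pearson_r", "p_value", "n")],
         ex_only = exonly[c("pearson_r", "p_value", "n")])
  }
}

#' Write / read empirical spike-count tables
#'
#' CSV schemas for unit data: FRA tables with columns \code{unit},
#' \code{freq_khz}, \code{level_db}, \code{rep}, \code{on_count},
#' \code{off_count}, \code{baseline_count}; sweep tables with
#' \code{unit}, \code{velocity}, \code{direction}, \code{rep},
#' \code{count}. [read_unit_tables()] reconstructs per-unit
#' [spike_fra()] / [sweep_spikes()] objects.
#'
#' @param units list of per-unit lists with \code{fra} and \code{sweeps}.
#' @param fra_path,sweep_path CSV file paths.
#' @return \code{write_unit_tables()}: invisibly, the two paths;
#'   \code{read_unit_tables()}: a list of per-unit lists.
#' @export
write_unit_tables <- function(units, fra_path, sweep_path) {
  fra_rows <- do.call(rbind, lapply(seq_along(units), function(k) {
    f <- units[[k]]$fra
    d <- dim(f$on_counts)
    grid <- expand.grid(fi = seq_len(d[1]), li = seq_len(d[2]),
                        rep = seq_len(d[3]))
    data.frame(unit = k, freq_khz = f$freq_axis[grid$fi],
               level_db = f$level_axis[grid$li], rep = grid$rep,
               on_count = f$on_counts[as.matrix(grid)],
               off_count = f$off_counts[as.matrix(grid)],
               baseline_count = f$baseline_counts[
                 (seq_len(nrow(grid)) - 1) %% length(f$baseline_counts) + 1])
  }))
  sweep_rows <- do.call(rbind, lapply(seq_along(units), function(k)
    cbind(unit = k, units[[k]]$sweeps$counts)))
  utils::write.csv(fra_rows, fra_path, row.names = FALSE)
  utils::write.csv(sweep_rows, sweep_path, row.names = FALSE)
  invisible(c(fra_path, sweep_path))
}

#' @rdname write_unit_tables
#' @export
read_unit_tables <- function(fra_path, sweep_path) {
  fra_rows <- utils::read.csv(fra_path)
  sweep_rows <- utils::read.csv(sweep_path)
  need <- c("unit", "freq_khz", "level_db", "rep", "on_count", "off_count",
            "baseline_count")
  if (!all(need %in% names(fra_rows)))
    stop("FRA table must have columns: ", paste(need, collapse = ", "))
  lapply(sort(unique(fra_rows$unit)), function(k) {
    fr <- fra_rows[fra_rows$unit == k, ]
    freqs <- sort(unique(fr$freq_khz))
    levels <- sort(unique(fr$level_db))
    reps <- sort(unique(fr$rep))
    idx <- cbind(match(fr$freq_khz, freqs), match(fr$level_db, levels),
                 match(fr$rep, reps))
    on <- array(0L, c(length(freqs), length(levels), length(reps)))
    off <- on
    on[idx] <- fr$on_count
    off[idx] <- fr$off_count
    sw <- sweep_rows[sweep_rows$unit == k,
                     c("velocity", "direction", "rep", "count")]
    list(fra = spike_fra(on, off, freqs, levels, fr$baseline_count),
         sweeps = sweep_spikes(sw))
  })
}

#' Unit metrics and DSI regression from CSV tables
#'
#' Reads FRA and sweep spike-count tables (schemas of
#' [write_unit_tables()]), computes every unit's functional properties,
#' and fits the full DSI regression. Units without defined ON and OFF
#' responses are dropped and counted.
#'
#' @param fra_path,sweep_path CSV file paths.
#' @param out_json optional path; when given, the regression report
#'   (coefficients, PRE, adjusted R-squared, n) is written as JSON.
#' @return list with \code{properties} (data.frame) and
#'   \code{regression} (see [fit_dsi_regression()]).
#' @export
unit_metrics_table <- function(fra_path, sweep_path, out_json = NULL) {
  units <- read_unit_tables(fra_path, sweep_path)
  props <- population_properties(units)
  if (is.null(props) || nrow(props) == 0)
    stop("no unit with defined ON and OFF responses")
  fit <- fit_dsi_regression(props)
  if (!is.null(out_json))
    jsonlite::write_json(
      list(coefficients = as.list(fit$coefficients),
           pre = as.list(fit$pre),
           adjusted_r2 = fit$adjusted_r2, n = fit$n,
           n_rejected = attr(props, "n_rejected")),
      out_json, auto_unbox = TRUE, digits = NA)
  list(properties = props, regression = fit)
}
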