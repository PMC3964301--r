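## Seeded replica ensembles: repeated constant-velocity pulls differing only
## in the random velocity assignment, per-replica summaries, aggregate
## Gaussian fits, and the pulling-speed scan. Replica seeds follow the
## documented scheme seed_i = base_seed + i - 1, so an ensemble is fully
## reproducible from its base seed and order-independent in aggregation.

#' Specify a pulling ensemble
#'
#' @param model A `go_model`.
#' @param protocol [pulling_protocol()]; `NULL` = defaults for the model.
#' @param params [simulation_params()] template; each replica gets its own
#'   seed.
#' @param n_replicas Number of replicas (>= 1).
#' @param base_seed Base seed; replica `i` runs with `base_seed + i - 1`.
#' @param ... Extra arguments forwarded to [run_cv_smd()] (e.g.
#'   `target_extension`, `equil_steps`, `record_every`).
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(model, protocol = NULL,
                          params = simulation_params(), n_replicas,
                          base_seed = 1L, ...) {
  stopifnot(inherits(model, "go_model"), n_replicas >= 1L)
  if (is.null(protocol)) protocol <- pulling_protocol(model)
  structure(list(model = model, protocol = protocol, params = params,
                 n_replicas = as.integer(n_replicas),
                 base_seed = as.integer(base_seed),
                 run_args = list(...)),
            class = "ensemble_spec")
}

#' Run a pulling ensemble
#'
#' Executes `n_replicas` independent constant-velocity pulls whose only
#' difference is the Maxwell-Boltzmann velocity seed, summarizes each trace
#' (maximum force, extension and time at the maximum, scenario label), and
#' fits the maximum-force distribution. A failing replica is recorded with
#' its error message and the ensemble continues.
#'
#' @param spec An [ensemble_spec()].
#' @param keep_traces Keep the full traces (memory permitting; needed for
#'   [average_curves()]).
#' @param smoothing_window Running-average window for trace summaries.
#' @param progress Print one line per replica to stderr.
#' @return An `ensemble_summary` list: `summaries` data frame (one row per
#'   successful replica: `seed`, `F_max_pN`, `rNC_nm`, `t_ns`, `scenario`),
#'   `fit` ([fit_force_distribution()] result or NULL if too few maxima),
#'   `failures` data frame, `traces` (list or NULL), `spec`.
#' @export
run_ensemble <- function(spec, keep_traces = FALSE, smoothing_window = 51L,
                         progress = FALSE) {
  stopifnot(inherits(spec, "ensemble_spec"))
  rows <- vector("list", spec$n_replicas)
  fails <- list()
  traces <- if (keep_traces) vector("list", spec$n_replicas) else NULL
  for (i in seq_len(spec$n_replicas)) {
    seed_i <- spec$base_seed + i - 1L
    params_i <- spec$params
    params_i$seed <- seed_i
    res <- tryCatch({
      tr <- do.call(run_cv_smd, c(list(model = spec$model,
                                       protocol = spec$protocol,
                                       params = params_i), spec$run_args))
      sm <- summarize_trace(tr, smoothing_window)
      sc <- suppressWarnings(classify_scenario(tr))
      if (keep_traces) traces[[i]] <- tr
      data.frame(seed = seed_i, F_max_pN = sm$F_max, rNC_nm = sm$r_NC_at_max,
                 t_ns = sm$t_at_max, scenario = sc$label,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        seed = seed_i, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- res
    }
    if (progress) {
      message(sprintf("replica %d/%d (seed %d) %s", i, spec$n_replicas,
                      seed_i,
                      if (inherits(res, "error")) "FAILED" else "done"))
    }
  }
  summaries <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  failures <- if (length(fails) > 0L) do.call(rbind, fails) else
    data.frame(seed = integer(0), reason = character(0))
  fit <- if (!is.null(summaries) && nrow(summaries) >= 10L) {
    fit_force_distribution(summaries$F_max_pN)
  } else NULL
  structure(list(summaries = summaries, fit = fit, failures = failures,
                 traces = traces, spec = spec),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  n_ok <- if (is.null(x$summaries)) 0L else nrow(x$summaries)
  cat(sprintf("ensemble_summary: %d/%d replicas, base seed %d\n",
              n_ok, x$spec$n_replicas, x$spec$base_seed))
  if (n_ok > 0L) {
    cat(sprintf("  F_max = %.1f +- %.1f pN\n", mean(x$summaries$F_max_pN),
                stats::sd(x$summaries$F_max_pN)))
  }
  if (nrow(x$failures) > 0L) {
    cat(sprintf("  %d failed replica(s)\n", nrow(x$failures)))
  }
  invisible(x)
}

#' Scan mean unfolding force over pulling speeds
#'
#' Runs one ensemble per pulling speed and tabulates the mean maximum force
#' with its standard error. A zero speed is accepted as a control entry: it
#' is flagged and excluded from any speed trend (`is_control = TRUE`), and
#' requires `target_extension`/`max_steps` via `...`. With a single replica
#' the standard error is reported as NA (undefined), not zero.
#'
#' Smoothing before the maximum search covers a fixed stretch of anchor
#' travel (`smoothing_travel`, default 1.275 A, i.e. the default 51-sample
#' window at the reference speed 0.025 A/ps), converted per speed into a
#' sample count. A fixed-duration window is not comparable across speeds: it
#' spans ten times more extension at a ten-fold faster pull (clipping its
#' rupture peaks harder), while slower runs record proportionally more
#' samples whose thermal force spikes inflate an unsmoothed or
#' under-smoothed maximum.
#'
#' @param model A `go_model`.
#' @param speeds Numeric vector of pulling speeds, A/ps (>= 2 values).
#' @param n_replicas Replicas per speed.
#' @param base_seed Base seed; speed `s` uses `base_seed + (s - 1) * n_replicas`
#'   so every replica in the scan has a distinct seed.
#' @param params [simulation_params()] template.
#' @param smoothing_travel Anchor travel covered by the running-average
#'   window, Angstrom.
#' @param ... Forwarded to [ensemble_spec()] / [run_cv_smd()].
#' @return Data frame: `speed_A_ps`, `mean_F_max_pN`, `se_F_max_pN`,
#'   `n`, `is_control`.
#' @export
speed_scan <- function(model, speeds, n_replicas = 20L, base_seed = 1L,
                       params = simulation_params(),
                       smoothing_travel = 1.275, ...) {
  stopifnot(length(speeds) >= 2L, all(speeds >= 0))
  dots <- list(...)
  cadence <- if (!is.null(dots$record_every)) dots$record_every else 100L
  rows <- vector("list", length(speeds))
  for (s in seq_along(speeds)) {
    sp <- speeds[s]
    if (sp == 0) {
      rows[[s]] <- data.frame(speed_A_ps = 0, mean_F_max_pN = NA_real_,
                              se_F_max_pN = NA_real_, n = 0L,
                              is_control = TRUE)
      next
    }
    win <- smoothing_travel / (sp * params$timestep * cadence)
    win <- max(1L, 2L * floor(win / 2) + 1L)
    protocol <- pulling_protocol(model, speed = sp)
    es <- ensemble_spec(model, protocol, params, n_replicas,
                        base_seed = base_seed + (s - 1L) * n_replicas, ...)
    ens <- run_ensemble(es, smoothing_window = win)
    fm <- ens$summaries$F_max_pN
    rows[[s]] <- data.frame(
      speed_A_ps = sp, mean_F_max_pN = mean(fm),
      se_F_max_pN = if (length(fm) >= 2L) stats::sd(fm) / sqrt(length(fm))
                    else NA_real_,
      n = length(fm), is_control = FALSE)
  }
  do.call(rbind, rows)
}

#' Write ensemble outputs
#'
#' Per-replica summary as CSV (one row per replica) and the aggregate report
#' (Gaussian fit parameters, failures) as JSON.
#'
#' @param ensemble An `ensemble_summary`.
#' @param csv_path,json_path Output paths (`NULL` skips the file).
#' @return Invisibly, the list written as JSON.
#' @export
write_ensemble_summary <- function(ensemble, csv_path = NULL,
                                   json_path = NULL) {
  stopifnot(inherits(ensemble, "ensemble_summary"))
  if (!is.null(csv_path)) {
    utils::write.csv(ensemble$summaries, csv_path, row.names = FALSE)
  }
  fm <- ensemble$summaries$F_max_pN
  report <- list(
    n_replicas = ensemble$spec$n_replicas,
    n_success = if (is.null(ensemble$summaries)) 0L else
      nrow(ensemble$summaries),
    base_seed = ensemble$spec$base_seed,
    mean_F_max_pN = if (length(fm)) mean(fm) else NA,
    sd_F_max_pN = if (length(fm) >= 2L) stats::sd(fm) else NA,
    fit = if (!is.null(ensemble$fit)) list(
      n_components = ensemble$fit$n_components,
      components = ensemble$fit$components,
      bic = as.list(ensemble$fit$bic)
    ) else NULL,
    failures = ensemble$failures
  )
  if (!is.null(json_path)) {
    writeLines(jsonlite::toJSON(report, dataframe = "rows", digits = NA,
                                auto_unbox = TRUE, pretty = TRUE, na = "null"),
               json_path)
  }
  invisible(report)
}
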