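#' Maximum adoption of a run
#'
#' Peak concurrent count of adopted (state I) nodes over the run, as a
#' fraction of the node count.  Ties in the peak resolve to the earliest
#' epoch (see `peak_epoch` on the run object).
#'
#' @param result a `dosage_run` object from [run_dosage()].
#' @param n_total node count; defaults to the run's own.
#' @return peak adopted fraction in `[0, 1]`.
#' @export
max_adoption <- function(result, n_total = result$n) {
  stopifnot(inherits(result, "dosage_run"), n_total >= 1)
  result$peak_I / n_total
}

#' Time to consensus of an SI-mode run
#'
#' First epoch at which the adopted fraction reaches `level`.  Only
#' meaningful for `si_mode` runs, where I is monotone so the time is
#' well-defined and monotone in `level`.
#'
#' @param result a `dosage_run` object from an `si_mode` run.
#' @param level consensus level in `(0, 1]` (the standard report levels are
#'   0.5, 0.74, 0.9 and 1.0).
#' @return first epoch with `I/N >= level`, or `NA` (censored) if the level
#'   was not reached within the micro-step budget.
#' @export
time_to_consensus <- function(result, level) {
  stopifnot(inherits(result, "dosage_run"), level > 0, level <= 1)
  if (!result$params$si_mode) {
    warning("time_to_consensus is defined for si_mode runs")
  }
  frac <- result$trajectory$I / result$n
  hit <- which(frac >= level)
  if (length(hit) == 0L) return(NA_real_)
  result$trajectory$epoch[hit[1L]]
}

#' Survival of the adopted population
#'
#' For an SIR run, the fraction of the peak adopted population still in
#' state I at each checkpoint epoch (`I(t)/I_max`), together with the raw
#' adopted fraction `I(t)/N`.  The peak is the maximum of the recorded
#' per-epoch trajectory (so survival is exactly 1 at the peak epoch, ties
#' to the earliest).  A checkpoint beyond the recorded horizon is reported
#' as `NA` (censored) unless the run went extinct, in which case the
#' surviving fraction is exactly 0 from the extinction epoch on.
#'
#' @param result a `dosage_run` object.
#' @param checkpoints numeric vector of epochs (e.g. 515).
#' @return data.frame with columns `epoch`, `survival` (`I(t)/I_max`),
#'   `raw` (`I(t)/N`) and `censored`; the trajectory peak count and its
#'   earliest epoch are attached as attributes `peak_I` and `peak_epoch`.
#' @export
survival_metrics <- function(result, checkpoints) {
  stopifnot(inherits(result, "dosage_run"))
  traj <- result$trajectory
  horizon <- max(traj$epoch)
  peak <- max(traj$I)
  extinct <- !is.na(result$extinction_epoch)
  out <- data.frame(epoch = checkpoints, survival = NA_real_,
                    raw = NA_real_, censored = FALSE)
  for (i in seq_along(checkpoints)) {
    t <- checkpoints[i]
    if (t <= horizon) {
      irow <- traj$I[which(traj$epoch >= t)[1L]]
      out$survival[i] <- if (peak > 0) irow / peak else NA_real_
      out$raw[i] <- irow / result$n
    } else if (extinct) {
      out$survival[i] <- 0
      out$raw[i] <- 0
    } else {
      out$censored[i] <- TRUE
    }
  }
  attr(out, "peak_I") <- peak
  attr(out, "peak_epoch") <- traj$epoch[which.max(traj$I)]
  out
}

#' Mean survival at a checkpoint over an ensemble
#'
#' Averages `I(t)/I_max` at epoch `t` over all replicates of an ensemble
#' (unconditionally, i.e. extinct runs contribute 0).  Requires the
#' ensemble to have been run with `keep_trajectories = TRUE`.
#'
#' @param ensemble a `dosage_ensemble` object with retained runs.
#' @param t checkpoint epoch.
#' @return list with `mean_survival` and `mean_raw` at epoch `t`.
#' @export
ensemble_survival_at <- function(ensemble, t) {
  stopifnot(inherits(ensemble, "dosage_ensemble"))
  if (is.null(ensemble$runs)) {
    stop("ensemble was run without keep_trajectories = TRUE")
  }
  sm <- vapply(ensemble$runs, function(run) {
    row <- survival_metrics(run, t)
    c(row$survival, row$raw)
  }, numeric(2))
  list(mean_survival = mean(sm[1L, ], na.rm = TRUE),
       mean_raw = mean(sm[2L, ], na.rm = TRUE))
}

#' Write run results to plain-text files
#'
#' Serializes a run's trajectory to CSV (`epoch, S, I, R`) and its scalar
#' metrics to JSON.
#'
#' @param result a `dosage_run` object.
#' @param csv_path,json_path output paths; `NULL` skips that output.
#' @return invisibly, the scalar metric list.
#' @export
write_run_result <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "dosage_run"))
  if (!is.null(csv_path)) {
    utils::write.csv(result$trajectory, csv_path, row.names = FALSE)
  }
  scalars <- list(n = result$n, peak_I = result$peak_I,
                  imax_fraction = result$peak_I / result$n,
                  peak_epoch = result$peak_epoch,
                  extinction_epoch = result$extinction_epoch,
                  consensus_epoch = result$consensus_epoch,
                  steps_done = result$steps_done,
                  master_seed = result$master_seed)
  if (!is.null(json_path)) {
    jsonlite::write_json(scalars, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(scalars)
}
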