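#' Specification of a multi-trial experiment
#'
#' A condition grid (by default the four +/-MI, +/-L2 combinations collapse
#' to the two the tasks contrast: with and without the MI term) crossed
#' with `n_trials` independent seeds per condition.  Trial j of every
#' condition uses seed `base_seed + j - 1`, so conditions are compared on
#' matched seed streams.
#'
#' @param cfg Prototype [training_config()] shared by all conditions.
#' @param conditions Named list of override lists (fields of
#'   `training_config` to replace, typically `lambda_I` / `lambda_reg`).
#' @param n_trials Trials per condition.
#' @param base_seed First trial seed.
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(cfg, conditions = NULL, n_trials = 20L,
                            base_seed = 1L) {
  stopifnot(inherits(cfg, "training_config"), n_trials >= 1)
  if (is.null(conditions)) {
    conditions <- list(mi = list(lambda_I = cfg$lambda_I),
                       no_mi = list(lambda_I = 0))
  }
  stopifnot(!is.null(names(conditions)), all(nzchar(names(conditions))))
  structure(list(cfg = cfg, conditions = conditions,
                 n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed)),
            class = "experiment_spec")
}

apply_overrides <- function(cfg, overrides) {
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

final_metric_names <- c("Q_cor", "Q_str", "D_cor", "D_out", "D_in",
                        "L_task", "R2", "correct_fraction", "I_hat", "I_n")

#' Run a multi-trial experiment over a condition grid
#'
#' Runs `n_trials` independent [run_trial()] calls per condition and
#' aggregates final-epoch metrics (mean and n-1 standard deviation over
#' trials), success counts, and a two-sample t-test contrast of each
#' metric between the first two conditions.  Failed trials (non-finite
#' loss) are recorded and excluded from aggregates.
#'
#' @param spec An [experiment_spec()].
#' @param verbose Print per-trial progress.
#' @return A list of class `midiff_experiment` with `trials` (list of
#'   trial lists per condition), `aggregate` (long data frame), `contrasts`,
#'   and `failures`.
#' @export
run_experiment <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  trials <- list()
  failures <- list()
  for (cond in names(spec$conditions)) {
    cfg_c <- apply_overrides(spec$cfg, spec$conditions[[cond]])
    trials[[cond]] <- list()
    for (j in seq_len(spec$n_trials)) {
      cfg_j <- cfg_c
      cfg_j$seed <- spec$base_seed + j - 1L
      if (verbose) message(sprintf("condition %s, trial %d (seed %d)",
                                   cond, j, cfg_j$seed))
      tr <- tryCatch(run_trial(cfg_j),
                     midiff_trial_failure = function(e) e)
      if (inherits(tr, "midiff_trial")) {
        trials[[cond]][[j]] <- tr
      } else {
        failures[[length(failures) + 1L]] <-
          list(condition = cond, trial = j, seed = cfg_j$seed,
               message = conditionMessage(tr))
        trials[[cond]][j] <- list(NULL)
      }
    }
  }
  agg <- aggregate_trials(trials)
  contrasts <- NULL
  if (length(trials) >= 2) {
    contrasts <- condition_contrasts(trials[[1]], trials[[2]],
                                     names(trials)[1:2])
  }
  structure(list(spec = spec, trials = trials, aggregate = agg,
                 contrasts = contrasts, failures = failures),
            class = "midiff_experiment")
}

final_metric_matrix <- function(trial_list) {
  ok <- Filter(Negate(is.null), trial_list)
  do.call(rbind, lapply(ok, function(tr) {
    vapply(final_metric_names, function(nm) {
      v <- tr$final[[nm]]
      if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
    }, numeric(1))
  }))
}

aggregate_trials <- function(trials) {
  rows <- list()
  for (cond in names(trials)) {
    mm <- final_metric_matrix(trials[[cond]])
    if (is.null(mm) || nrow(mm) == 0) next
    n_ok <- nrow(mm)
    succ <- vapply(Filter(Negate(is.null), trials[[cond]]),
                   function(tr) isTRUE(tr$success), logical(1))
    for (nm in colnames(mm)) {
      v <- mm[, nm]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, metric = nm, n = length(v),
        mean = if (length(v) > 0) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, metric = "success_rate", n = n_ok,
      mean = mean(succ), sd = NA_real_)
  }
  do.call(rbind, rows)
}

condition_contrasts <- function(a, b, cond_names) {
  ma <- final_metric_matrix(a)
  mb <- final_metric_matrix(b)
  if (is.null(ma) || is.null(mb)) return(NULL)
  rows <- list()
  for (nm in colnames(ma)) {
    va <- ma[, nm][is.finite(ma[, nm])]
    vb <- mb[, nm][is.finite(mb[, nm])]
    if (length(va) >= 2 && length(vb) >= 2 &&
        (stats::sd(va) > 0 || stats::sd(vb) > 0)) {
      tt <- stats::t.test(va, vb)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = nm, cond_a = cond_names[1], cond_b = cond_names[2],
        mean_a = mean(va), mean_b = mean(vb),
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  if (length(rows) == 0) NULL else do.call(rbind, rows)
}

#' Mean metric time courses across trials
#'
#' Assembles per-evaluation-point mean curves of the modularity and
#' separability metrics across a list of trials, optionally restricted to
#' trials whose final functional modularity exceeds a threshold (the
#' "robust differentiation" rule, default `Q_cor > 0.1`).
#'
#' @param trials List of [run_trial()] results (aligned schedules).
#' @param filter_robust Keep only trials with final `Q_cor > q_threshold`.
#' @param q_threshold Robustness threshold on final `Q_cor`.
#' @return Data frame with `iter` and mean curves (`Q_cor`, `Q_str`,
#'   `D_cor`, `D_out`, `D_in`), plus attribute `"n_trials"`.
#' @export
timecourse_report <- function(trials, filter_robust = FALSE,
                              q_threshold = 0.1) {
  trials <- Filter(Negate(is.null), trials)
  stopifnot(length(trials) >= 1)
  if (filter_robust) {
    keep <- vapply(trials, function(tr) tr$final$Q_cor > q_threshold,
                   logical(1))
    trials <- trials[keep]
    if (length(trials) == 0) stop("no trials pass the robustness filter")
  }
  iters <- trials[[1]]$timecourse$iter
  for (tr in trials) {
    if (!identical(tr$timecourse$iter, iters)) {
      stop("trials have misaligned evaluation schedules")
    }
  }
  cols <- c("Q_cor", "Q_str", "D_cor", "D_out", "D_in")
  out <- data.frame(iter = iters)
  for (cl in cols) {
    vals <- vapply(trials, function(tr) tr$timecourse[[cl]],
                   numeric(length(iters)))
    out[[cl]] <- rowMeans(as.matrix(vals))
  }
  attr(out, "n_trials") <- length(trials)
  out
}

#' Half-rise evaluation point of a metric curve
#'
#' The first evaluation iteration at which the curve reaches half of its
#' final value; used to compare when functional vs structural modularity
#' develop.
#'
#' @param iter Evaluation iterations.
#' @param values Metric values at those iterations.
#' @return The iteration of first half-rise (NA if the curve never
#'   reaches it or ends non-positive).
#' @export
half_rise <- function(iter, values) {
  stopifnot(length(iter) == length(values))
  fin <- values[length(values)]
  if (!is.finite(fin) || fin <= 0) return(NA_real_)
  idx <- which(values >= fin / 2)
  if (length(idx) == 0) NA_real_ else iter[idx[1]]
}

#' Write the artifacts of one trial to a directory
#'
#' Emits the per-iteration loss breakdown and metric time course as CSV and
#' a JSON summary of the final metrics and configuration scalars.
#'
#' @param trial A [run_trial()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "midiff_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$losses, file.path(dir, "losses.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$timecourse, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  write_checkpoint(trial$params, trial$readout,
                   file.path(dir, "checkpoint.json"), trial$cfg, trial$T_net)
  if (!is.null(trial$final$corr_graph)) {
    utils::write.csv(trial$final$corr_graph,
                     file.path(dir, "correlation_matrix.csv"),
                     row.names = FALSE)
  }
  W <- if (inherits(trial$params, "leaky_params")) trial$params$Wrec
       else trial$params$Uc
  utils::write.csv(W, file.path(dir, "recurrent_weights.csv"),
                   row.names = FALSE)
  fin <- trial$final[final_metric_names]
  fin <- fin[!vapply(fin, is.null, logical(1))]
  cfg <- trial$cfg[vapply(trial$cfg, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), logical(1))]
  jsonlite::write_json(list(seed = trial$seed, success = trial$success,
                            final = fin, config = cfg),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
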