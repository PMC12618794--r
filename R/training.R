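#' Training configuration for one adversarial trial
#'
#' Bundles the task, architecture, loss weights, adversarial schedule, and
#' problem sizes for a single training trial.  The adversarial schedule is
#' asymmetric: the critic (SM) is pretrained for `sm_pretrain`
#' iterations, then each main-model (MM) update is preceded by `sm_per_mm`
#' critic ascent iterations.  Evaluation runs on held-out batches drawn
#' from a seed stream disjoint from training.
#'
#' @param task `"wm"` (working memory, leaky-integrator RNN) or `"sep"`
#'   (chaotic signal separation, GRU).
#' @param N Recurrent units (must be even).
#' @param n_batch Training sequences per mini-batch.
#' @param L_train,transient_train Training sequence length and excluded
#'   transient (transient applies to the working-memory task only).
#' @param L_eval,transient_eval,n_eval Held-out evaluation sequence length,
#'   transient, and batch size.
#' @param lambda_I Weight of the mutual-information term (0 disables the
#'   critic entirely).
#' @param lambda_reg Weight of the L2 penalty.
#' @param mm_iterations Number of MM update cycles.
#' @param sm_pretrain Critic-only iterations before MM training starts.
#' @param sm_per_mm Critic iterations per MM update.
#' @param lr_mm,lr_sm Adam learning rates for MM and SM.
#' @param sm_hidden Hidden widths of the critic.
#' @param sm_minibatch Pooled (batch x time) samples per critic iteration.
#' @param mi_minibatch Pooled samples used for the MM's MI gradient
#'   (`NULL` = the full pooled rollout).
#' @param sigma_noise SD of the Gaussian noise added to critic inputs.
#' @param grad_clip Global-norm clip for MM gradients.
#' @param eval_every Evaluate metrics every this many MM cycles.
#' @param seed Trial seed; the whole trial is a deterministic function of it.
#' @param alpha,noise_scale Leaky RNN leak rate and state-noise SD.
#' @param p_pulse,pulse_width Pulse statistics of the working-memory task.
#' @param lorenz,rossler Chaotic system specs for the separation task.
#' @return A list of class `training_config`.
#' @export
training_config <- function(task = c("wm", "sep"),
                            N = if (task == "wm") 64L else 128L,
                            n_batch = 32L,
                            L_train = if (task == "wm") 2000L else 500L,
                            transient_train = if (task == "wm") 1000L else 0L,
                            L_eval = if (task == "wm") 2000L else 500L,
                            transient_eval = if (task == "wm") 1000L else 0L,
                            n_eval = 8L,
                            lambda_I = 0.1, lambda_reg = 1e-4,
                            mm_iterations = 500L,
                            sm_pretrain = 100L, sm_per_mm = 20L,
                            lr_mm = 1e-3, lr_sm = 1e-3,
                            sm_hidden = c(128L, 128L), sm_minibatch = 512L,
                            mi_minibatch = NULL,
                            sigma_noise = 0.1, grad_clip = 10,
                            eval_every = 20L, seed = 1L,
                            alpha = 0.1, noise_scale = 0.1,
                            p_pulse = 0.002, pulse_width = 40L,
                            lorenz = NULL, rossler = NULL) {
  task <- match.arg(task)
  stopifnot(N %% 2L == 0L, lambda_I >= 0, lambda_reg >= 0,
            sm_pretrain >= 0, sm_per_mm >= 1, mm_iterations >= 1)
  if (task == "sep") {
    if (is.null(lorenz)) lorenz <- chaotic_system_spec("lorenz")
    if (is.null(rossler)) rossler <- chaotic_system_spec("rossler")
  }
  structure(list(
    task = task, arch = if (task == "wm") "leaky" else "gru",
    M = if (task == "wm") 1L else 3L, N_in = if (task == "wm") 4L else 3L,
    N = as.integer(N), n_batch = as.integer(n_batch),
    L_train = as.integer(L_train), transient_train = as.integer(transient_train),
    L_eval = as.integer(L_eval), transient_eval = as.integer(transient_eval),
    n_eval = as.integer(n_eval),
    lambda_I = lambda_I, lambda_reg = lambda_reg,
    mm_iterations = as.integer(mm_iterations),
    sm_pretrain = as.integer(sm_pretrain), sm_per_mm = as.integer(sm_per_mm),
    lr_mm = lr_mm, lr_sm = lr_sm,
    sm_hidden = as.integer(sm_hidden), sm_minibatch = as.integer(sm_minibatch),
    mi_minibatch = if (is.null(mi_minibatch)) NULL else as.integer(mi_minibatch),
    sigma_noise = sigma_noise, grad_clip = grad_clip,
    eval_every = as.integer(eval_every), seed = as.integer(seed),
    alpha = alpha, noise_scale = noise_scale,
    p_pulse = p_pulse, pulse_width = as.integer(pulse_width),
    lorenz = lorenz, rossler = rossler
  ), class = "training_config")
}

mm_flatten <- function(arch, params, readout) {
  keep <- if (arch == "leaky") c("Wrec", "Win", "b") else
    c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wc", "Uc", "bc")
  c(params[keep], readout[c("Wy1", "by1", "Wy2", "by2")])
}

mm_unflatten <- function(arch, params, readout, flat) {
  keep <- if (arch == "leaky") c("Wrec", "Win", "b") else
    c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wc", "Uc", "bc")
  for (nm in keep) params[[nm]] <- flat[[nm]]
  for (nm in c("Wy1", "by1", "Wy2", "by2")) readout[[nm]] <- flat[[nm]]
  list(params = params, readout = readout)
}

gen_train_batch <- function(cfg, seed) {
  if (cfg$task == "wm") {
    tc <- wm_task_config(p_pulse = cfg$p_pulse, pulse_width = cfg$pulse_width,
                         L = cfg$L_train, transient = cfg$transient_train,
                         n_batch = cfg$n_batch)
    b <- generate_wm_batch(tc, seed)
    list(X = aperm(b$inputs, c(2, 3, 1)),      # (N_in, nb, L)
         T1 = aperm(b$targets[, 1, , drop = FALSE], c(2, 3, 1)),
         T2 = aperm(b$targets[, 2, , drop = FALSE], c(2, 3, 1)),
         targets = b$targets)
  } else {
    b <- generate_separation_batch(cfg$lorenz, cfg$rossler, cfg$n_batch,
                                   cfg$L_train, seed)
    list(X = aperm(b$mixed_input, c(2, 3, 1)),
         T1 = aperm(b$target_lorenz, c(2, 3, 1)),
         T2 = aperm(b$target_rossler, c(2, 3, 1)),
         batch = b)
  }
}

gen_eval_batch <- function(cfg, seed) {
  if (cfg$task == "wm") {
    tc <- wm_task_config(p_pulse = cfg$p_pulse, pulse_width = cfg$pulse_width,
                         L = cfg$L_eval, transient = cfg$transient_eval,
                         n_batch = cfg$n_eval)
    b <- generate_wm_batch(tc, seed)
    list(X = aperm(b$inputs, c(2, 3, 1)),
         T1 = aperm(b$targets[, 1, , drop = FALSE], c(2, 3, 1)),
         T2 = aperm(b$targets[, 2, , drop = FALSE], c(2, 3, 1)),
         targets = b$targets)
  } else {
    b <- generate_separation_batch(cfg$lorenz, cfg$rossler, cfg$n_eval,
                                   cfg$L_eval, seed)
    list(X = aperm(b$mixed_input, c(2, 3, 1)),
         T1 = aperm(b$target_lorenz, c(2, 3, 1)),
         T2 = aperm(b$target_rossler, c(2, 3, 1)),
         batch = b)
  }
}

pool_states <- function(H, N) t(matrix(H, N, length(H) / N))

draw_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

# One critic ascent iteration on a random subsample of the pooled rollout
# states, with fresh input noise and a fresh shuffle.
sm_iteration <- function(T_net, sm_opt, pooled, cfg, groups) {
  n <- nrow(pooled)
  idx <- sample.int(n, min(cfg$sm_minibatch, n))
  noisy <- add_input_noise(pooled[idx, , drop = FALSE], cfg$sigma_noise,
                           draw_seed())
  joint <- paired_samples(noisy, groups)
  shuf <- shuffle_pairs(joint, draw_seed())
  sm_update(T_net, joint, shuf, sm_opt, cfg$lr_sm)
}

# Task-loss value and dLoss/dY arrays for a rollout (batch-averaged).
task_grads <- function(cfg, roll, batch) {
  nb <- roll$nb
  L <- roll$L
  if (cfg$task == "wm") {
    keep <- (cfg$transient_train + 1):L
    Lp <- length(keep)
    dY1 <- array(0, dim = dim(roll$Y1))
    dY2 <- array(0, dim = dim(roll$Y2))
    e1 <- roll$Y1[, , keep, drop = FALSE] - batch$T1[, , keep, drop = FALSE]
    e2 <- roll$Y2[, , keep, drop = FALSE] - batch$T2[, , keep, drop = FALSE]
    dY1[, , keep] <- e1 / (nb * Lp)
    dY2[, , keep] <- e2 / (nb * Lp)
    loss <- (sum(e1^2) + sum(e2^2)) / (2 * Lp * nb)
  } else {
    e1 <- roll$Y1 - batch$T1
    e2 <- roll$Y2 - batch$T2
    dY1 <- e1 / (nb * L)
    dY2 <- e2 / (nb * L)
    loss <- (sum(e1^2) + sum(e2^2)) / (2 * L * nb)
  }
  list(loss = loss, dY1 = dY1, dY2 = dY2)
}

# One MM descent step; returns updated parameter sets and the loss breakdown.
mm_iteration <- function(cfg, params, readout, T_net, mm_opt, groups) {
  batch <- gen_train_batch(cfg, draw_seed())
  roll <- rollout_batch(cfg$arch, params, readout, batch$X)
  N <- roll$N
  nbl <- roll$nb * roll$L
  tg <- task_grads(cfg, roll, batch)
  Am <- matrix(roll$A, N, nbl)
  dY1m <- matrix(tg$dY1, cfg$M, nbl)
  dY2m <- matrix(tg$dY2, cfg$M, nbl)
  dA <- crossprod(readout$Wy1, dY1m) + crossprod(readout$Wy2, dY2m)

  i_hat <- NA_real_
  dH_mi <- NULL
  if (cfg$lambda_I > 0) {
    pooled <- pool_states(roll$H, N)
    idx <- seq_len(nbl)
    if (!is.null(cfg$mi_minibatch) && cfg$mi_minibatch < nbl) {
      idx <- sample.int(nbl, cfg$mi_minibatch)
    }
    noisy <- add_input_noise(pooled[idx, , drop = FALSE], cfg$sigma_noise,
                             draw_seed())
    joint <- paired_samples(noisy, groups)
    shuf <- shuffle_pairs(joint, draw_seed())
    gi <- dv_gradients(T_net, joint, shuf, want_inputs = TRUE)
    i_hat <- gi$estimate$value
    # the subsampled DV objective is an unbiased surrogate for the pooled
    # one, so its per-slot gradients enter unscaled at their slots
    dH_mi <- matrix(0, nbl, N)
    dH_mi[idx, groups == 1L] <- gi$dh1
    dH_mi[idx, groups == 2L] <- gi$dh2
  }

  # external gradient w.r.t. the hidden state at every step
  if (cfg$arch == "leaky") {
    dH <- dA * (1 - Am^2)  # dLoss/da -> dLoss/dh through a = tanh(h)
  } else {
    dH <- dA
  }
  if (!is.null(dH_mi)) dH <- dH + cfg$lambda_I * t(dH_mi)
  dH_ext <- array(dH, dim = c(N, roll$nb, roll$L))

  if (cfg$arch == "leaky") {
    bp <- cpp_leaky_bptt(params$Wrec, params$alpha, batch$X, roll$A, dH_ext)
    grads <- list(Wrec = bp$dWrec, Win = bp$dWin, b = drop(bp$db))
  } else {
    bp <- cpp_gru_bptt(params$Uz, params$Ur, params$Uc, batch$X, roll$H,
                       roll$Z, roll$Rg, roll$Hc, dH_ext)
    grads <- list(Wz = bp$dWz, Uz = bp$dUz, bz = drop(bp$dbz),
                  Wr = bp$dWr, Ur = bp$dUr, br = drop(bp$dbr),
                  Wc = bp$dWc, Uc = bp$dUc, bc = drop(bp$dbc))
    if (!isTRUE(params$gate_bias)) {
      grads$bz[] <- 0
      grads$br[] <- 0
      grads$bc[] <- 0
    }
  }
  grads$Wy1 <- tcrossprod(dY1m, Am)
  grads$by1 <- rowSums(dY1m)
  grads$Wy2 <- tcrossprod(dY2m, Am)
  grads$by2 <- rowSums(dY2m)

  flat <- mm_flatten(cfg$arch, params, readout)
  reg <- l2_penalty(flat)
  for (nm in grep("^(W|U)", names(flat), value = TRUE)) {
    grads[[nm]] <- grads[[nm]] + cfg$lambda_reg * flat[[nm]]
  }
  grads <- grads[names(flat)]
  grads <- clip_global_norm(grads, cfg$grad_clip)
  lb <- total_loss(tg$loss, reg, if (is.na(i_hat)) 0 else i_hat,
                   cfg$lambda_reg, cfg$lambda_I)
  lb$I_hat <- i_hat
  if (!is.finite(lb$total)) {
    stop(structure(class = c("midiff_trial_failure", "error", "condition"),
                   list(message = "non-finite training loss", call = NULL,
                        breakdown = lb)))
  }
  upd <- adam_step(mm_opt, flat, grads, cfg$lr_mm)
  uf <- mm_unflatten(cfg$arch, params, readout, upd$params)
  list(params = uf$params, readout = uf$readout, opt = upd$state,
       breakdown = lb)
}

# Metric evaluation on the held-out batch (noise drawn from a dedicated
# evaluation seed so the training stream is untouched).
evaluate_model <- function(cfg, params, readout, T_net, eval_batch,
                           eval_seed, groups, final = FALSE) {
  roll <- withr::with_seed(eval_seed, {
    rollout_batch(cfg$arch, params, readout, eval_batch$X)
  })
  N <- roll$N
  nb <- roll$nb
  L <- roll$L
  keep <- (cfg$transient_eval + 1):L
  # pooled post-transient activity and outputs (time within sequence, then
  # sequences concatenated)
  a_keep <- roll$A[, , keep, drop = FALSE]
  a_pool <- t(matrix(aperm(a_keep, c(1, 3, 2)), N, nb * length(keep)))
  y1_pool <- t(matrix(aperm(roll$Y1[, , keep, drop = FALSE], c(1, 3, 2)),
                      cfg$M, nb * length(keep)))
  y2_pool <- t(matrix(aperm(roll$Y2[, , keep, drop = FALSE], c(1, 3, 2)),
                      cfg$M, nb * length(keep)))
  corg <- correlation_graph(a_pool)
  q_cor <- newman_modularity(corg, groups)
  W_str <- if (cfg$arch == "leaky") params$Wrec else params$Uc
  q_str <- newman_modularity(structural_graph(W_str), groups)
  cmat <- neuron_output_correlations(a_pool, y1_pool, y2_pool)
  met <- list(
    Q_cor = q_cor, Q_str = q_str,
    D_cor = d_cor(cmat, groups),
    D_out = d_out(readout$Wy1, readout$Wy2, groups),
    D_in = if (cfg$task == "wm") d_in(params$Win, groups) else NA_real_
  )
  if (cfg$task == "wm") {
    loss <- 0
    correct <- 0
    for (b in seq_len(nb)) {
      y <- cbind(roll$Y1[1, b, ], roll$Y2[1, b, ])
      tgt <- eval_batch$targets[, , b]
      loss <- loss + wm_task_loss(y, tgt, cfg$transient_eval)
      correct <- correct + wm_correct_fraction(y, tgt, cfg$transient_eval)
    }
    met$L_task <- loss / nb
    met$correct_fraction <- correct / nb
    met$success <- met$correct_fraction > 0.9
    met$R2 <- NA_real_
  } else {
    loss <- 0
    r2 <- c()
    for (b in seq_len(nb)) {
      y1 <- t(roll$Y1[, b, ])
      y2 <- t(roll$Y2[, b, ])
      x1 <- t(eval_batch$T1[, b, ])
      x2 <- t(eval_batch$T2[, b, ])
      loss <- loss + separation_task_loss(y1, y2, x1, x2)
      r2 <- c(r2,
              vapply(1:3, function(k) r_squared(x1[, k], y1[, k]), numeric(1)),
              vapply(1:3, function(k) r_squared(x2[, k], y2[, k]), numeric(1)))
    }
    met$L_task <- loss / nb
    met$R2 <- mean(r2)
    met$correct_fraction <- NA_real_
    met$success <- NA
  }
  if (!is.null(T_net)) {
    pooled <- pool_states(roll$H, N)
    noisy <- withr::with_seed(eval_seed + 1L, {
      pooled + stats::rnorm(length(pooled), 0, cfg$sigma_noise)
    })
    joint <- paired_samples(noisy, groups)
    shuf <- shuffle_pairs(joint, eval_seed + 2L)
    met$I_hat <- dv_estimate(T_net, joint, shuf)$value
  } else {
    met$I_hat <- NA_real_
  }
  if (final) {
    comm <- tryCatch(detect_communities(corg), error = function(e) NULL)
    met$I_n <- if (is.null(comm)) NA_real_ else {
      tryCatch(normalized_mi(groups, comm), error = function(e) NA_real_)
    }
    met$communities <- comm
    met$c_mat <- cmat
    met$corr_graph <- corg
  }
  met
}

#' Run one adversarial training trial
#'
#' Executes the full schedule: critic pretraining (`sm_pretrain`
#' iterations), then repeated blocks of `sm_per_mm` critic ascent
#' iterations followed by one main-model descent step on the total loss
#' \eqn{L = L_{task} + \lambda_{reg} L_{reg} + \lambda_I \hat I}.  A fresh
#' training mini-batch (and rollout) is generated for every critic block
#' and every MM step; within a block the critic draws fresh subsamples,
#' input noise, and shuffles from the pooled rollout states.  When
#' `lambda_I = 0` the critic is skipped entirely.  Metrics are evaluated on
#' a fixed held-out batch every `eval_every` MM cycles using a seed stream
#' disjoint from training.  The whole trial is a deterministic function of
#' `cfg$seed`.
#'
#' @param cfg A [training_config()].
#' @param verbose Print progress every evaluation.
#' @return A list of class `midiff_trial`: final `params`, `readout`,
#'   `T_net`, per-MM-iteration loss breakdowns (`losses`), the metric
#'   `timecourse` data frame, `final` metrics (including the community
#'   detection validation), and the trial `success` flag.
#' @export
run_trial <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "training_config"))
  groups <- group_assignment(cfg$N)
  eval_seed <- cfg$seed + 900001L
  eval_batch <- gen_eval_batch(cfg, eval_seed)
  set.seed(cfg$seed)

  if (cfg$arch == "leaky") {
    params <- init_leaky_params(cfg$N, cfg$N_in, cfg$alpha, cfg$noise_scale)
  } else {
    params <- init_gru_params(cfg$N, cfg$N_in)
  }
  readout <- init_readout(cfg$M, cfg$N)
  use_sm <- cfg$lambda_I > 0
  T_net <- if (use_sm) init_statistics_network(cfg$N, cfg$sm_hidden) else NULL
  sm_opt <- NULL
  mm_opt <- adam_init(mm_flatten(cfg$arch, params, readout))

  sm_block <- function(n_iter) {
    pooled <- NULL
    for (i in seq_len(n_iter)) {
      if ((i - 1L) %% cfg$sm_per_mm == 0L) {
        batch <- gen_train_batch(cfg, draw_seed())
        roll <- rollout_batch(cfg$arch, params, readout, batch$X)
        pooled <- pool_states(roll$H, cfg$N)
      }
      res <- sm_iteration(T_net, sm_opt, pooled, cfg, groups)
      T_net <<- res$T_net
      sm_opt <<- res$opt_state
    }
  }

  if (use_sm && cfg$sm_pretrain > 0) sm_block(cfg$sm_pretrain)

  losses <- vector("list", cfg$mm_iterations)
  tc_rows <- list()
  for (m in seq_len(cfg$mm_iterations)) {
    if (use_sm) sm_block(cfg$sm_per_mm)
    step <- mm_iteration(cfg, params, readout, T_net, mm_opt, groups)
    params <- step$params
    readout <- step$readout
    mm_opt <- step$opt
    losses[[m]] <- step$breakdown
    if (m %% cfg$eval_every == 0L || m == cfg$mm_iterations) {
      met <- evaluate_model(cfg, params, readout, T_net, eval_batch,
                            eval_seed + 10L * m, groups)
      tc_rows[[length(tc_rows) + 1L]] <-
        data.frame(iter = m, Q_cor = met$Q_cor, Q_str = met$Q_str,
                   D_cor = met$D_cor, D_out = met$D_out, D_in = met$D_in,
                   I_hat = met$I_hat, L_task = met$L_task, R2 = met$R2,
                   correct_fraction = met$correct_fraction)
      if (verbose) {
        message(sprintf(
          "iter %d: L_task=%.3f Q_cor=%.3f Q_str=%.3f D_cor=%.3f I=%.3f",
          m, met$L_task, met$Q_cor, met$Q_str, met$D_cor,
          ifelse(is.na(met$I_hat), 0, met$I_hat)))
      }
    }
  }
  final <- evaluate_model(cfg, params, readout, T_net, eval_batch,
                          eval_seed + 10L * cfg$mm_iterations + 1L, groups,
                          final = TRUE)
  losses_df <- do.call(rbind, lapply(seq_along(losses), function(i) {
    lb <- losses[[i]]
    data.frame(iter = i, L_task = lb$L_task, L_reg = lb$L_reg,
               I_hat = lb$I_hat, total = lb$total)
  }))
  structure(list(cfg = cfg, seed = cfg$seed, params = params,
                 readout = readout, T_net = T_net,
                 n_sm_iterations = if (is.null(sm_opt)) 0L else sm_opt$t,
                 losses = losses_df,
                 timecourse = do.call(rbind, tc_rows),
                 final = final, success = final$success),
            class = "midiff_trial")
}
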