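#' Configuration for the 2-bit working-memory pulse task
#'
#' Four input channels (ON1, OFF1, ON2, OFF2) carry brief pulses; the network
#' must hold two independent +/-1 memory bits, flipping bit j to +1 at an
#' ON_j pulse onset and to -1 at an OFF_j onset.  Defaults follow the benchmark
#' conditions: onset probability 0.002 per step per channel, pulse width 40
#' steps, amplitude 1.0, sequences of 2,000 steps with a 1,000-step
#' transient excluded from loss and metrics.
#'
#' @param p_pulse Onset probability per time step per channel.
#' @param pulse_width Pulse duration in steps.
#' @param amplitude Pulse height.
#' @param L Sequence length in steps.
#' @param transient Leading steps excluded from the task loss.
#' @param n_batch Sequences per mini-batch.
#' @return A list of class `wm_task_config`.
#' @export
wm_task_config <- function(p_pulse = 0.002, pulse_width = 40, amplitude = 1.0,
                           L = 2000, transient = 1000, n_batch = 32) {
  stopifnot(p_pulse >= 0, p_pulse <= 1, pulse_width >= 1, L >= 1,
            transient >= 0, transient < L, n_batch >= 1)
  structure(list(n_channels = 4L, p_pulse = p_pulse,
                 pulse_width = as.integer(pulse_width), amplitude = amplitude,
                 L = as.integer(L), transient = as.integer(transient),
                 n_batch = as.integer(n_batch)),
            class = "wm_task_config")
}

wm_one_sequence <- function(cfg) {
  L <- cfg$L
  w <- cfg$pulse_width
  onsets <- matrix(stats::rbinom(L * 4L, 1L, cfg$p_pulse), nrow = L, ncol = 4L)
  # a channel is high at t if any onset occurred in (t - w, t]; overlapping
  # pulses on one channel therefore extend the high period
  cum <- apply(onsets, 2, cumsum)
  lagged <- rbind(matrix(0, min(w, L), 4L),
                  cum[seq_len(max(L - w, 0L)), , drop = FALSE])
  inputs <- cfg$amplitude * ((cum - lagged) > 0)
  init <- sample(c(-1, 1), 2L, replace = TRUE)
  targets <- matrix(0, L, 2L)
  for (j in 1:2) {
    ev <- numeric(L)
    ev[onsets[, 2L * j - 1L] == 1L] <- 1   # ON_j
    ev[onsets[, 2L * j] == 1L] <- -1       # OFF_j; simultaneous ON/OFF -> OFF wins
    pos <- which(ev != 0)
    if (length(pos) == 0) {
      targets[, j] <- init[j]
    } else {
      targets[, j] <- c(init[j], ev[pos])[findInterval(seq_len(L), pos) + 1L]
    }
  }
  list(inputs = inputs, targets = targets, onsets = onsets)
}

#' Generate a mini-batch of working-memory pulse sequences
#'
#' Pulse onsets are independent Bernoulli draws per channel and step; each
#' onset holds its channel at `amplitude` for `pulse_width` steps.  The
#' target for bit j flips to +1 at ON_j onsets and to -1 at OFF_j onsets
#' (OFF wins a simultaneous onset on both channels of one bit) and holds
#' otherwise.  Before the first pulse, each bit starts at a random +/-1
#' state drawn from the same seeded generator.
#'
#' @param cfg A [wm_task_config()].
#' @param seed Integer seed; the batch is a deterministic function of it.
#' @return List with `inputs` (`L x 4 x n_batch`), `targets`
#'   (`L x 2 x n_batch`, entries -1/+1), `onsets`, and the config.
#' @export
generate_wm_batch <- function(cfg, seed) {
  stopifnot(inherits(cfg, "wm_task_config"))
  withr::with_seed(as.integer(seed), {
    inputs <- array(0, dim = c(cfg$L, 4L, cfg$n_batch))
    targets <- array(0, dim = c(cfg$L, 2L, cfg$n_batch))
    onsets <- array(0L, dim = c(cfg$L, 4L, cfg$n_batch))
    for (b in seq_len(cfg$n_batch)) {
      sq <- wm_one_sequence(cfg)
      inputs[, , b] <- sq$inputs
      targets[, , b] <- sq$targets
      onsets[, , b] <- sq$onsets
    }
    list(inputs = inputs, targets = targets, onsets = onsets,
         seed = as.integer(seed), cfg = cfg)
  })
}
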