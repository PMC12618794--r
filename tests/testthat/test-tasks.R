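test_that("pulse-free configuration yields silent inputs and held targets", {
  cfg <- wm_task_config(p_pulse = 0, L = 200, transient = 50, n_batch = 3)
  b <- generate_wm_batch(cfg, 1)
  expect_true(all(b$inputs == 0))
  for (s in 1:3) {
    for (j in 1:2) {
      expect_equal(length(unique(b$targets[, j, s])), 1L)
      expect_true(all(b$targets[, j, s] %in% c(-1, 1)))
    }
  }
})

test_that("batches are deterministic in the seed and respect the contract", {
  cfg <- wm_task_config(p_pulse = 0.01, pulse_width = 7, L = 400,
                        transient = 100, n_batch = 4)
  b1 <- generate_wm_batch(cfg, 99)
  b2 <- generate_wm_batch(cfg, 99)
  expect_identical(b1, b2)
  b3 <- generate_wm_batch(cfg, 100)
  expect_false(identical(b1$inputs, b3$inputs))

  # inputs take only {0, amplitude} and match the onset windows exactly
  for (s in 1:4) {
    for (ch in 1:4) {
      onsets <- which(b1$onsets[, ch, s] == 1)
      high <- rep(FALSE, cfg$L)
      for (o in onsets) high[o:min(cfg$L, o + cfg$pulse_width - 1L)] <- TRUE
      expect_equal(b1$inputs[, ch, s], cfg$amplitude * high)
    }
  }
})

test_that("targets flip at own-bit onsets only, with OFF winning ties", {
  cfg <- wm_task_config(p_pulse = 0.02, L = 300, transient = 50, n_batch = 6)
  b <- generate_wm_batch(cfg, 7)
  for (s in 1:6) {
    for (j in 1:2) {
      tr <- b$targets[, j, s]
      expect_true(all(tr %in% c(-1, 1)))
      on <- b$onsets[, 2 * j - 1, s] == 1
      off <- b$onsets[, 2 * j, s] == 1
      expected_change <- on | off
      changes <- c(FALSE, diff(tr) != 0)
      # a change may only happen at an own-bit onset
      expect_true(all(!changes | expected_change))
      # value after an onset follows the pulse type, OFF dominating
      expect_true(all(tr[off] == -1))
      expect_true(all(tr[on & !off] == 1))
      # pulses on this bit leave the other bit's target untouched
      other <- b$targets[, 3 - j, s]
      other_onset <- b$onsets[, 2 * (3 - j) - 1, s] == 1 |
        b$onsets[, 2 * (3 - j), s] == 1
      other_changes <- c(FALSE, diff(other) != 0)
      expect_true(all(!other_changes | other_onset))
    }
  }
})

test_that("pulse onset counts match the Binomial law", {
  cfg <- wm_task_config(p_pulse = 0.002, L = 2000, transient = 1000,
                        n_batch = 500)
  counts <- integer(0)
  for (seed in 1:20) {
    b <- generate_wm_batch(cfg, seed)
    counts <- c(counts, apply(b$onsets, c(2, 3), sum))
  }
  # 20 x 500 sequences x 4 channels = 4e4 Binomial(2000, 0.002) draws
  n <- length(counts)
  mu <- cfg$L * cfg$p_pulse
  se <- sqrt(cfg$L * cfg$p_pulse * (1 - cfg$p_pulse) / n)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # chi-squared goodness of fit with tail pooling (expected count >= 5)
  kmax <- max(counts)
  probs <- dbinom(0:kmax, cfg$L, cfg$p_pulse)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  while (n * probs[length(probs)] < 5 && length(probs) > 2) {
    k <- length(probs)
    probs[k - 1] <- probs[k - 1] + probs[k]
    obs[k - 1] <- obs[k - 1] + obs[k]
    probs <- probs[-k]
    obs <- obs[-k]
  }
  probs[length(probs)] <- probs[length(probs)] + (1 - sum(probs))
  pval <- suppressWarnings(chisq.test(obs, p = probs)$p.value)
  expect_gt(pval, 0.01)
})

test_that("chaotic right-hand sides match direct substitution", {
  lp <- list(sigma = 10, rho = 28, beta = 8 / 3)
  expect_equal(lorenz_rhs(c(1, 1, 1), lp), c(0, 26, -8 / 3 + 1))
  # fixed point of the Lorenz flow: beta * (rho - 1) = 72
  eq <- c(sqrt(72), sqrt(72), 27)
  expect_equal(lorenz_rhs(eq, lp), c(0, 0, 0), tolerance = 1e-12)
  rp <- list(a = 0.2, b = 0.2, c = 5.7)
  expect_equal(rossler_rhs(c(1, 2, 3), rp),
               c(-5, 1 + 0.4, 0.2 + 3 * (1 - 5.7)))
})

test_that("a trajectory started at the Lorenz equilibrium stays there", {
  spec <- chaotic_system_spec("lorenz", warmup = 0, dt = 0.01)
  traj <- integrate_system(spec, c(sqrt(72), sqrt(72), 27), 200)
  expect_lt(max(abs(sweep(traj, 2, c(sqrt(72), sqrt(72), 27)))), 1e-8)
})

test_that("nearby Lorenz trajectories diverge (positive Lyapunov exponent)", {
  spec <- chaotic_system_spec("lorenz", warmup = 0)
  x0 <- c(1, 1, 20)
  t1 <- integrate_system(spec, x0, 1500)
  t2 <- integrate_system(spec, x0 + c(1e-8, 0, 0), 1500)
  d <- sqrt(rowSums((t1 - t2)^2))
  expect_lt(d[1], 1e-6)
  expect_gt(max(d), 1)  # separation reaches attractor scale
  # average log-distance growth is positive over the early window
  expect_gt(mean(diff(log(d[1:500]))), 0)
})

test_that("integrator error shrinks at the Runge-Kutta order when dt halves", {
  x0 <- c(2, -1, 25)
  horizon <- 2  # time units
  ref <- integrate_system(chaotic_system_spec("lorenz", dt = 0.0005,
                                              warmup = 0),
                          x0, horizon / 0.0005)
  err <- function(dt) {
    tr <- integrate_system(chaotic_system_spec("lorenz", dt = dt, warmup = 0),
                           x0, horizon / dt)
    sqrt(sum((tr[nrow(tr), ] - ref[nrow(ref), ])^2))
  }
  e1 <- err(0.02)
  e2 <- err(0.01)
  # global error O(dt^4): halving dt should shrink it about 16-fold
  expect_gt(e1 / e2, 8)
  expect_lt(e1 / e2, 32)
})

test_that("separation batches mix standardized components exactly", {
  lor <- chaotic_system_spec("lorenz", warmup = 200)
  ros <- chaotic_system_spec("rossler", warmup = 200)
  b1 <- generate_separation_batch(lor, ros, n_batch = 2, L = 300, seed = 5)
  b2 <- generate_separation_batch(lor, ros, n_batch = 2, L = 300, seed = 5)
  expect_identical(b1, b2)
  expect_equal(b1$mixed_input, b1$target_lorenz + b1$target_rossler)
  # standardized components have roughly zero mean and unit variance
  long <- generate_separation_batch(lor, ros, n_batch = 1, L = 6000, seed = 6)
  for (k in 1:3) {
    expect_lt(abs(mean(long$target_lorenz[, k, 1])), 0.3)
    expect_lt(abs(sd(long$target_lorenz[, k, 1]) - 1), 0.3)
    expect_lt(abs(sd(long$target_rossler[, k, 1]) - 1), 0.5)
  }
})
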