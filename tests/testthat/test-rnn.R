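test_that("leaky step reproduces hand-computed updates", {
  p <- list(alpha = 0.1, Wrec = matrix(0, 1, 1), Win = matrix(0, 1, 1), b = 0)
  expect_equal(leaky_step(p, 1, 0, 0), 0.9)  # pure leak
  p$Win <- matrix(1, 1, 1)
  expect_equal(leaky_step(p, 0, 1, 0), 0.1)  # direct substitution
  p2 <- list(alpha = 1, Wrec = matrix(0, 2, 2), Win = diag(2), b = c(0, 0))
  expect_equal(leaky_step(p2, c(5, -2), c(0.3, 0.7), c(0, 0)), c(0.3, 0.7))
})

test_that("gru step reproduces gate limit cases", {
  N <- 3
  zero <- function() matrix(0, N, N)
  p <- list(Wz = zero(), Uz = zero(), bz = numeric(N),
            Wr = zero(), Ur = zero(), br = numeric(N),
            Wc = zero(), Uc = zero(), bc = numeric(N))
  h <- c(1, -2, 0.5)
  # all-zero parameters: z = 0.5, candidate 0, so the state halves
  expect_equal(gru_step(p, h, numeric(N)), 0.5 * h)
  # update gate forced shut: perfect hold
  p_hold <- p
  p_hold$bz <- rep(-50, N)
  expect_equal(gru_step(p_hold, h, numeric(N)), h)
  # update gate forced open: state jumps to the candidate
  p_jump <- p
  p_jump$bz <- rep(50, N)
  p_jump$bc <- c(1, 2, 3)
  expect_equal(gru_step(p_jump, h, numeric(N)), tanh(c(1, 2, 3)))
})

test_that("rollouts match the per-step reference implementations", {
  set.seed(21)
  N <- 6
  Nin <- 4
  L <- 15
  inputs <- matrix(rnorm(L * Nin), L, Nin)

  p <- init_leaky_params(N, Nin, alpha = 0.3, noise_scale = 0.05)
  tr <- run_model("leaky", p, init_readout(2, N), inputs, seed = 5)
  # regenerate the same noise stream and iterate leaky_step by hand
  h_ref <- matrix(0, L, N)
  withr::with_seed(5L, {
    noise <- array(rnorm(N * L, 0, p$noise_scale), dim = c(N, 1, L))
    h <- numeric(N)
    for (t in 1:L) {
      h <- leaky_step(p, h, inputs[t, ], noise[, 1, t])
      h_ref[t, ] <- h
    }
  })
  expect_equal(tr$h, h_ref, tolerance = 1e-12)
  expect_equal(tr$a, tanh(h_ref), tolerance = 1e-12)

  g <- init_gru_params(N, Nin)
  tg <- run_model("gru", g, init_readout(2, N), inputs, seed = 5)
  h <- numeric(N)
  for (t in 1:L) {
    h <- gru_step(g, h, inputs[t, ])
    expect_equal(tg$h[t, ], h, tolerance = 1e-12)
  }
  expect_equal(tg$a, tg$h)
})

test_that("trajectories honor the readout contract and determinism", {
  set.seed(22)
  N <- 8
  p <- init_leaky_params(N, 4, noise_scale = 0.1)
  ro <- init_readout(1, N)
  inputs <- matrix(rnorm(40), 10, 4)
  t1 <- run_model("leaky", p, ro, inputs, seed = 9)
  t2 <- run_model("leaky", p, ro, inputs, seed = 9)
  expect_identical(t1, t2)
  expect_equal(t1$y1, t(ro$Wy1 %*% t(t1$a) + ro$by1), tolerance = 1e-12)
  # zero readout weights pin the outputs at the bias
  ro0 <- ro
  ro0$Wy1 <- matrix(0, 1, N)
  ro0$by1 <- 0.7
  t3 <- run_model("leaky", p, ro0, inputs, seed = 9)
  expect_equal(t3$y1, matrix(0.7, 10, 1))
})

test_that("zero-drive leaky dynamics decay geometrically at rate 1 - alpha", {
  N <- 4
  p <- init_leaky_params(N, 2, alpha = 0.25, noise_scale = 0)
  p$Wrec[] <- 0
  p$Win[] <- 0
  p$b[] <- 0
  h0 <- c(1, -1, 2, 0.5)
  tr <- run_model("leaky", p, init_readout(1, N), matrix(0, 6, 2),
                  h0 = h0, seed = 1)
  for (t in 1:6) expect_equal(tr$h[t, ], 0.75^t * h0, tolerance = 1e-12)
})

test_that("leaky RNN with alpha 1 and no noise is the classic tanh RNN", {
  set.seed(23)
  N <- 5
  p <- init_leaky_params(N, 3, alpha = 1, noise_scale = 0)
  inputs <- matrix(rnorm(30), 10, 3)
  tr <- run_model("leaky", p, init_readout(1, N), inputs, seed = 2)
  h <- numeric(N)
  for (t in 1:10) {
    h <- drop(p$Wrec %*% tanh(h) + p$Win %*% inputs[t, ] + p$b)
    expect_equal(tr$h[t, ], h, tolerance = 1e-12)
  }
})

test_that("BPTT gradients match central finite differences", {
  set.seed(24)
  N <- 5
  Nin <- 3
  nb <- 2
  L <- 3
  M <- 2
  X <- array(rnorm(Nin * nb * L), dim = c(Nin, nb, L))
  noise <- array(0, dim = c(N, nb, L))
  Wy <- matrix(rnorm(M * N), M, N)
  targ <- array(rnorm(M * nb * L), dim = c(M, nb, L))

  check_arch <- function(arch, params, names) {
    fwd <- function(pl) {
      if (arch == "leaky") {
        midiff:::cpp_leaky_forward(pl$Wrec, pl$Win, pl$b, pl$alpha, X, noise,
                                   numeric(N))$R
      } else {
        midiff:::cpp_gru_forward(pl$Wz, pl$Uz, pl$bz, pl$Wr, pl$Ur, pl$br,
                                 pl$Wc, pl$Uc, pl$bc, X, numeric(N))$H
      }
    }
    loss <- function(pl) {
      A <- fwd(pl)
      sum((array(Wy %*% matrix(A, N, nb * L), dim = c(M, nb, L)) - targ)^2) / 2
    }
    grads <- local({
      if (arch == "leaky") {
        fw <- midiff:::cpp_leaky_forward(params$Wrec, params$Win, params$b,
                                         params$alpha, X, noise, numeric(N))
        A <- fw$R
        dY <- array(Wy %*% matrix(A, N, nb * L), dim = c(M, nb, L)) - targ
        dH <- crossprod(Wy, matrix(dY, M, nb * L)) * (1 - matrix(A, N, nb * L)^2)
        midiff:::cpp_leaky_bptt(params$Wrec, params$alpha, X, A,
                                array(dH, dim = c(N, nb, L)))
      } else {
        fw <- midiff:::cpp_gru_forward(params$Wz, params$Uz, params$bz,
                                       params$Wr, params$Ur, params$br,
                                       params$Wc, params$Uc, params$bc, X,
                                       numeric(N))
        dY <- array(Wy %*% matrix(fw$H, N, nb * L), dim = c(M, nb, L)) - targ
        dH <- crossprod(Wy, matrix(dY, M, nb * L))
        midiff:::cpp_gru_bptt(params$Uz, params$Ur, params$Uc, X, fw$H, fw$Z,
                              fw$Rg, fw$Hc, array(dH, dim = c(N, nb, L)))
      }
    })
    for (nm in names) {
      g <- grads[[paste0("d", nm)]]
      for (i in seq_len(min(6, length(params[[nm]])))) {
        eps <- 1e-5
        p1 <- params
        p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params
        p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (loss(p1) - loss(p2)) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(1e-6, abs(num)), 1e-4)
      }
    }
  }

  check_arch("leaky", init_leaky_params(N, Nin, alpha = 0.3, noise_scale = 0),
             c("Wrec", "Win", "b"))
  check_arch("gru", init_gru_params(N, Nin),
             c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wc", "Uc", "bc"))
})

test_that("run_model flags non-finite states with the failing step", {
  p <- init_leaky_params(2, 2, alpha = 1, noise_scale = 0)
  p$Win <- matrix(1e308, 2, 2)
  p$Wrec[] <- 0
  inputs <- matrix(c(0, 0, 1e10, 1e10, 0, 0), 3, 2, byrow = TRUE)
  expect_error(run_model("leaky", p, init_readout(1, 2), inputs, seed = 1),
               "non-finite state at step")
})
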