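#' Initialize leaky-integrator RNN parameters
#'
#' Recurrent weights are Gaussian with standard deviation `rec_gain/sqrt(N)`,
#' input weights Gaussian with standard deviation `1/sqrt(N_in)`, biases
#' zero.  Draws come from the caller's RNG stream; seed before calling for
#' reproducibility.
#'
#' @param N Number of recurrent units.
#' @param N_in Number of input channels.
#' @param alpha Leak rate in (0, 1]; the state decays toward its driven
#'   value at this rate per step.
#' @param noise_scale Standard deviation of the per-step, per-neuron
#'   Gaussian state noise.
#' @param rec_gain Spectral scale of the recurrent initialization.
#' @return Named list of parameter arrays (class `leaky_params`).
#' @export
init_leaky_params <- function(N, N_in, alpha = 0.1, noise_scale = 0.1,
                              rec_gain = 1.0) {
  stopifnot(alpha > 0, alpha <= 1, noise_scale >= 0)
  structure(list(
    Wrec = matrix(stats::rnorm(N * N, 0, rec_gain / sqrt(N)), N, N),
    Win = matrix(stats::rnorm(N * N_in, 0, 1 / sqrt(N_in)), N, N_in),
    b = numeric(N),
    alpha = alpha, noise_scale = noise_scale
  ), class = "leaky_params")
}

#' Initialize GRU parameters
#'
#' All weight matrices use the standard uniform fan-in initialization
#' U(-1/sqrt(N), 1/sqrt(N)); gate and candidate biases are included and
#' start at zero (set `gate_bias = FALSE` to freeze them at zero).
#'
#' @inheritParams init_leaky_params
#' @param gate_bias Train the gate/candidate biases (default TRUE).
#' @return Named list of parameter arrays (class `gru_params`).
#' @export
init_gru_params <- function(N, N_in, gate_bias = TRUE) {
  k <- 1 / sqrt(N)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  structure(list(
    Wz = u(N, N_in), Uz = u(N, N), bz = numeric(N),
    Wr = u(N, N_in), Ur = u(N, N), br = numeric(N),
    Wc = u(N, N_in), Uc = u(N, N), bc = numeric(N),
    gate_bias = isTRUE(gate_bias)
  ), class = "gru_params")
}

#' Initialize the dual linear readout
#'
#' Two independent affine readouts of the recurrent-layer output, each of
#' dimension M (1 for the working-memory task, 3 for the separation task).
#'
#' @param M Output dimension per readout head.
#' @param N Number of recurrent units.
#' @return Named list with `Wy1`, `by1`, `Wy2`, `by2` (class `readout_params`).
#' @export
init_readout <- function(M, N) {
  structure(list(
    Wy1 = matrix(stats::rnorm(M * N, 0, 1 / sqrt(N)), M, N), by1 = numeric(M),
    Wy2 = matrix(stats::rnorm(M * N, 0, 1 / sqrt(N)), M, N), by2 = numeric(M)
  ), class = "readout_params")
}

#' One leaky-integrator update step
#'
#' \eqn{h = (1-\alpha) h_{prev} + \alpha (W_{rec} \tanh(h_{prev}) +
#' W_{in} x + b + \xi)}.
#'
#' @param p A [init_leaky_params()] list.
#' @param h_prev State vector (length N).
#' @param x Input vector (length N_in).
#' @param noise Noise vector \eqn{\xi} (length N).
#' @return Updated state vector.
#' @export
leaky_step <- function(p, h_prev, x, noise) {
  stopifnot(length(h_prev) == nrow(p$Wrec), length(x) == ncol(p$Win),
            length(noise) == length(h_prev))
  drop((1 - p$alpha) * h_prev +
         p$alpha * (p$Wrec %*% tanh(h_prev) + p$Win %*% x + p$b + noise))
}

#' One GRU update step
#'
#' Update gate \eqn{z = \sigma(W_z x + U_z h_{prev} + b_z)}, reset gate
#' \eqn{r = \sigma(W_r x + U_r h_{prev} + b_r)}, candidate
#' \eqn{\tilde h = \tanh(W x + U (r \odot h_{prev}) + b)}, state
#' \eqn{h = (1-z) \odot h_{prev} + z \odot \tilde h}.
#'
#' @param p A [init_gru_params()] list.
#' @param h_prev State vector (length N).
#' @param x Input vector (length N_in).
#' @return Updated state vector.
#' @export
gru_step <- function(p, h_prev, x) {
  stopifnot(length(h_prev) == nrow(p$Uz), length(x) == ncol(p$Wz))
  sig <- function(a) 1 / (1 + exp(-a))
  z <- sig(p$Wz %*% x + p$Uz %*% h_prev + p$bz)
  r <- sig(p$Wr %*% x + p$Ur %*% h_prev + p$br)
  hc <- tanh(p$Wc %*% x + p$Uc %*% (r * h_prev) + p$bc)
  drop((1 - z) * h_prev + z * hc)
}

# Batched rollout.  X: array (N_in, n_batch, L).  Returns state/activity
# cubes (N, n_batch, L) plus readouts computed per step.  Noise is drawn
# from the caller's RNG stream (leaky RNN only).
rollout_batch <- function(arch, params, readout, X) {
  dims <- dim(X)
  nb <- dims[2]
  L <- dims[3]
  if (arch == "leaky") {
    N <- nrow(params$Wrec)
    noise <- array(stats::rnorm(N * nb * L, 0, params$noise_scale),
                   dim = c(N, nb, L))
    fw <- cpp_leaky_forward(params$Wrec, params$Win, params$b, params$alpha,
                            X, noise, numeric(N))
    H <- fw$H
    A <- fw$R
    extra <- list(noise = noise)
  } else if (arch == "gru") {
    N <- nrow(params$Uz)
    fw <- cpp_gru_forward(params$Wz, params$Uz, params$bz,
                          params$Wr, params$Ur, params$br,
                          params$Wc, params$Uc, params$bc, X, numeric(N))
    H <- fw$H
    A <- fw$H
    extra <- list(Z = fw$Z, Rg = fw$Rg, Hc = fw$Hc)
  } else {
    stop("unknown architecture: ", arch)
  }
  Am <- matrix(A, N, nb * L)
  Y1 <- readout$Wy1 %*% Am + readout$by1
  Y2 <- readout$Wy2 %*% Am + readout$by2
  c(list(H = H, A = A, X = X,
         Y1 = array(Y1, dim = c(nrow(Y1), nb, L)),
         Y2 = array(Y2, dim = c(nrow(Y2), nb, L)),
         arch = arch, N = N, nb = nb, L = L), extra)
}

#' Run a model over one input sequence
#'
#' Full rollout of a leaky-integrator RNN or GRU from `h0` with the dual
#' readout applied at every step.  The leaky RNN receives fresh Gaussian
#' state noise per neuron and step; the GRU is noiseless.  Deterministic
#' given the seed.
#'
#' @param arch `"leaky"` or `"gru"`.
#' @param params Parameters from [init_leaky_params()] or [init_gru_params()].
#' @param readout Parameters from [init_readout()].
#' @param inputs `L x N_in` input matrix.
#' @param h0 Initial state (default zeros).
#' @param seed Integer seed for the state noise.
#' @return List (class `midiff_trajectory`) with `h` (`L x N` states),
#'   `a` (`L x N` recurrent-layer output: `tanh(h)` for the leaky RNN,
#'   `h` for the GRU), and readouts `y1`, `y2` (`L x M`).
#' @export
run_model <- function(arch = c("leaky", "gru"), params, readout, inputs,
                      h0 = NULL, seed = 1L) {
  arch <- match.arg(arch)
  stopifnot(is.matrix(inputs))
  L <- nrow(inputs)
  N <- if (arch == "leaky") nrow(params$Wrec) else nrow(params$Uz)
  if (is.null(h0)) h0 <- numeric(N)
  X <- array(t(inputs), dim = c(ncol(inputs), 1L, L))
  withr::with_seed(as.integer(seed), {
    if (arch == "leaky") {
      noise <- array(stats::rnorm(N * L, 0, params$noise_scale),
                     dim = c(N, 1L, L))
      fw <- cpp_leaky_forward(params$Wrec, params$Win, params$b,
                              params$alpha, X, noise, h0)
      H <- fw$H
      A <- fw$R
    } else {
      fw <- cpp_gru_forward(params$Wz, params$Uz, params$bz,
                            params$Wr, params$Ur, params$br,
                            params$Wc, params$Uc, params$bc, X, h0)
      H <- fw$H
      A <- fw$H
    }
  })
  bad <- which(!is.finite(apply(H, 3, sum)))
  if (length(bad) > 0) {
    stop("non-finite state at step ", bad[1])
  }
  h <- t(matrix(H, N, L))
  a <- t(matrix(A, N, L))
  list2 <- structure(list(
    h = h, a = a,
    y1 = t(readout$Wy1 %*% t(a) + readout$by1),
    y2 = t(readout$Wy2 %*% t(a) + readout$by2),
    arch = arch
  ), class = "midiff_trajectory")
  list2
}
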