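#' Right-hand sides of the two chaotic systems
#'
#' Canonical Lorenz equations \eqn{\dot x = \sigma(y - x)},
#' \eqn{\dot y = x(\rho - z) - y}, \eqn{\dot z = xy - \beta z} and Roessler
#' equations \eqn{\dot x = -y - z}, \eqn{\dot y = x + a y},
#' \eqn{\dot z = b + z(x - c)}.
#'
#' @param state Numeric 3-vector (x, y, z).
#' @param params Named list of system parameters.
#' @return Numeric 3-vector of derivatives.
#' @export
lorenz_rhs <- function(state, params) {
  c(params$sigma * (state[2] - state[1]),
    state[1] * (params$rho - state[3]) - state[2],
    state[1] * state[2] - params$beta * state[3])
}

#' @rdname lorenz_rhs
#' @export
rossler_rhs <- function(state, params) {
  c(-state[2] - state[3],
    state[1] + params$a * state[2],
    params$b + state[3] * (state[1] - params$c))
}

#' Specification of a chaotic ODE system for the separation task
#'
#' Parameters default to the canonical chaotic regimes (Lorenz sigma = 10,
#' rho = 28, beta = 8/3; Roessler a = 0.2, b = 0.2, c = 5.7).  Integration
#' is fixed-step 4th-order Runge-Kutta; `warmup` steps are discarded so
#' trajectories start on the attractor.  The Roessler time step is larger
#' because its oscillation period is roughly an order of magnitude longer
#' than the Lorenz one.
#'
#' @param name `"lorenz"` or `"rossler"`.
#' @param params Named list of system parameters (canonical defaults).
#' @param dt Integration step in system time units.
#' @param warmup Integration steps discarded before the trajectory starts.
#' @param init_range 3 x 2 matrix of uniform sampling bounds for initial
#'   conditions (rows = x, y, z).
#' @return A list of class `chaotic_system_spec`.
#' @export
chaotic_system_spec <- function(name = c("lorenz", "rossler"), params = NULL,
                                dt = NULL, warmup = 1000, init_range = NULL) {
  name <- match.arg(name)
  if (is.null(params)) {
    params <- switch(name,
                     lorenz = list(sigma = 10, rho = 28, beta = 8 / 3),
                     rossler = list(a = 0.2, b = 0.2, c = 5.7))
  }
  if (is.null(dt)) dt <- switch(name, lorenz = 0.02, rossler = 0.1)
  if (is.null(init_range)) {
    init_range <- switch(name,
                         lorenz = cbind(c(-10, -15, 10), c(10, 15, 30)),
                         rossler = cbind(c(-5, -5, 0), c(5, 5, 5)))
  }
  stopifnot(dt > 0, warmup >= 0)
  structure(list(name = name, params = params, dt = dt,
                 integrator = "rk4", warmup = as.integer(warmup),
                 init_range = init_range),
            class = "chaotic_system_spec")
}

spec_rhs <- function(spec) {
  switch(spec$name, lorenz = lorenz_rhs, rossler = rossler_rhs)
}

#' Integrate a chaotic system with fixed-step RK4
#'
#' Solves the named system from `x0` with the classical 4th-order
#' Runge-Kutta method at spacing `spec$dt` (via `deSolve`), discards
#' `spec$warmup` steps, and returns the next `n_steps` states.  A
#' trajectory that leaves the representable range raises a classed error
#' (`midiff_divergence`) carrying the first bad step index.
#'
#' @param spec A [chaotic_system_spec()].
#' @param x0 Finite numeric 3-vector initial condition.
#' @param n_steps Number of post-warmup steps to return.
#' @return `n_steps x 3` matrix of states.
#' @export
integrate_system <- function(spec, x0, n_steps) {
  stopifnot(inherits(spec, "chaotic_system_spec"), length(x0) == 3,
            all(is.finite(x0)), n_steps >= 1)
  rhs <- spec_rhs(spec)
  fn <- function(t, y, parms) list(rhs(y, parms))
  times <- seq(0, by = spec$dt, length.out = spec$warmup + n_steps + 1L)
  sol <- deSolve::rk4(y = x0, times = times, func = fn, parms = spec$params)
  traj <- unname(sol[(spec$warmup + 2L):(spec$warmup + n_steps + 1L), 2:4,
                     drop = FALSE])
  bad <- which(!apply(is.finite(traj), 1, all) | apply(abs(traj), 1, max) > 1e6)
  if (length(bad) > 0) {
    stop(structure(class = c("midiff_divergence", "error", "condition"),
                   list(message = sprintf("trajectory diverged at step %d", bad[1]),
                        call = NULL, step = bad[1])))
  }
  traj
}

moments_cache <- new.env(parent = emptyenv())

#' Long-run per-channel moments of a chaotic system
#'
#' Means and standard deviations of (x, y, z) over a single long reference
#' trajectory started from the midpoint of the sampling box at a fixed
#' internal seed.  Used to standardize components before mixing so that
#' neither system dominates the sum; cached per (system, parameters, dt).
#'
#' @param spec A [chaotic_system_spec()].
#' @param n_ref Reference trajectory length in steps.
#' @return List with `mean` and `sd`, each a 3-vector.
#' @export
system_moments <- function(spec, n_ref = 20000) {
  key <- paste(spec$name, paste(unlist(spec$params), collapse = ","),
               spec$dt, n_ref, sep = "|")
  if (!is.null(moments_cache[[key]])) return(moments_cache[[key]])
  x0 <- rowMeans(spec$init_range) + c(0.13, -0.07, 0.21)  # fixed off-center start
  traj <- integrate_system(spec, x0, n_ref)
  m <- list(mean = colMeans(traj), sd = apply(traj, 2, stats::sd))
  moments_cache[[key]] <- m
  m
}

standardize_traj <- function(traj, moments) {
  sweep(sweep(traj, 2, moments$mean, "-"), 2, moments$sd, "/")
}

#' Generate a mini-batch for the chaotic signal separation task
#'
#' For each batch element, one Lorenz and one Roessler trajectory are
#' integrated from independently sampled initial conditions, standardized
#' per channel with the long-run moments of each system, and summed into
#' the 3-channel mixed input.  The standardized components are the targets,
#' so `mixed = target_lorenz + target_rossler` holds exactly.  Divergent
#' trajectories are resampled (up to `max_retries` fresh initial
#' conditions).
#'
#' @param lorenz,rossler [chaotic_system_spec()] objects.
#' @param n_batch Number of trajectory pairs.
#' @param L Sequence length in steps.
#' @param seed Integer seed; the batch is a deterministic function of it.
#' @param standardize Standardize components before mixing (default TRUE).
#' @param max_retries Resampling attempts per divergent trajectory.
#' @return List with `mixed_input`, `target_lorenz`, `target_rossler`
#'   (each `L x 3 x n_batch`) and the seed.
#' @export
generate_separation_batch <- function(lorenz, rossler, n_batch, L, seed,
                                      standardize = TRUE, max_retries = 5) {
  stopifnot(n_batch >= 1, L >= 2)
  ml <- if (standardize) system_moments(lorenz)
  mr <- if (standardize) system_moments(rossler)
  withr::with_seed(as.integer(seed), {
    tl <- array(0, dim = c(L, 3L, n_batch))
    tr <- array(0, dim = c(L, 3L, n_batch))
    draw <- function(spec, mom) {
      for (attempt in seq_len(max_retries + 1L)) {
        x0 <- stats::runif(3, spec$init_range[, 1], spec$init_range[, 2])
        traj <- tryCatch(integrate_system(spec, x0, L),
                         midiff_divergence = function(e) NULL)
        if (!is.null(traj)) {
          if (standardize) traj <- standardize_traj(traj, mom)
          return(traj)
        }
      }
      stop("repeated divergent trajectories for system ", spec$name)
    }
    for (b in seq_len(n_batch)) {
      tl[, , b] <- draw(lorenz, ml)
      tr[, , b] <- draw(rossler, mr)
    }
    list(mixed_input = tl + tr, target_lorenz = tl, target_rossler = tr,
         seed = as.integer(seed))
  })
}
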