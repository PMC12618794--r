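#' Initialize the statistics network (critic)
#'
#' A scalar-valued feed-forward ReLU network \eqn{T_\theta(h^{(1)}, h^{(2)})}
#' on the concatenated subgroup states.  He-style Gaussian initialization
#' for the weights, zero biases.  Draws come from the caller's RNG stream.
#'
#' @param input_dim Length of the concatenated input (N).
#' @param hidden Integer vector of hidden-layer widths.
#' @return List (class `statistics_network`) with weight list `W` and bias
#'   list `b` (weights are out x in).
#' @export
init_statistics_network <- function(input_dim, hidden = c(128, 128)) {
  sizes <- c(input_dim, hidden, 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(sizes[l + 1L] * fan_in, 0, sqrt(2 / fan_in)),
                     sizes[l + 1L], fan_in)
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(W = W, b = b, input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden)),
            class = "statistics_network")
}

#' Evaluate the statistics network
#'
#' @param T_net A [init_statistics_network()] object.
#' @param X `n x input_dim` matrix, one sample (concatenated pair) per row.
#' @return Numeric vector of n scalar outputs.
#' @export
statistics_network_forward <- function(T_net, X) {
  stopifnot(is.matrix(X), ncol(X) == T_net$input_dim)
  drop(cpp_mlp_forward(T_net$W, T_net$b, X))
}

#' Pool paired subgroup states
#'
#' Splits pooled recurrent states (one row per batch x time slot) into the
#' two fixed subgroup blocks.
#'
#' @param states `n x N` matrix of pooled hidden states.
#' @param groups Group labels from [group_assignment()].
#' @return List (class `paired_samples`) with `h1`, `h2` and `n`.
#' @export
paired_samples <- function(states, groups) {
  stopifnot(is.matrix(states), ncol(states) == length(groups))
  structure(list(h1 = states[, groups == 1L, drop = FALSE],
                 h2 = states[, groups == 2L, drop = FALSE],
                 n = nrow(states)),
            class = "paired_samples")
}

#' Add Gaussian noise to critic inputs
#'
#' Independent zero-mean Gaussian perturbation of every element, used to
#' stabilize critic training; `sigma_noise = 0` is the identity.
#'
#' @param states Numeric array or matrix.
#' @param sigma_noise Noise standard deviation (non-negative).
#' @param seed Integer seed.
#' @return Perturbed array of the same shape.
#' @export
add_input_noise <- function(states, sigma_noise, seed) {
  stopifnot(sigma_noise >= 0)
  if (sigma_noise == 0) return(states)
  withr::with_seed(as.integer(seed), {
    states + stats::rnorm(length(states), 0, sigma_noise)
  })
}

#' Shuffle pairs to emulate the product of marginals
#'
#' Permutes the second-group states uniformly across the pooled
#' batch x time slots while the first-group states stay in place.  The
#' marginal multisets are preserved exactly; only the pairing is broken.
#'
#' @param samples A [paired_samples()] object.
#' @param seed Integer seed.
#' @return A `paired_samples` object with permuted `h2` and the permutation
#'   attached as attribute `"perm"`.
#' @export
shuffle_pairs <- function(samples, seed) {
  stopifnot(inherits(samples, "paired_samples"))
  if (samples$n < 2) stop("need at least 2 samples to shuffle")
  perm <- withr::with_seed(as.integer(seed), sample.int(samples$n))
  out <- structure(list(h1 = samples$h1,
                        h2 = samples$h2[perm, , drop = FALSE],
                        n = samples$n),
                   class = "paired_samples")
  attr(out, "perm") <- perm
  out
}

logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Donsker-Varadhan estimate of mutual information
#'
#' \eqn{\hat I = E_{joint}[T] - \log E_{shuffled}[e^T]}: the first term is
#' the mean critic output over the original pairs, the second the
#' log-mean-exp (computed with max-subtraction for overflow safety) over
#' the shuffled pairs.  A lower bound on the true MI at the optimum over
#' critics.
#'
#' @param T_net A [init_statistics_network()] object.
#' @param joint A [paired_samples()] object (original pairing).
#' @param shuffled The shuffled counterpart from [shuffle_pairs()].
#' @return List (class `mi_estimate`) with `value`, `term_joint`,
#'   `term_marginal` (all in nats) and `n_samples`.
#' @export
dv_estimate <- function(T_net, joint, shuffled) {
  stopifnot(joint$n >= 2, shuffled$n == joint$n)
  t_joint <- statistics_network_forward(T_net, cbind(joint$h1, joint$h2))
  t_shuf <- statistics_network_forward(T_net, cbind(shuffled$h1, shuffled$h2))
  if (any(!is.finite(t_joint)) || any(!is.finite(t_shuf))) {
    stop("statistics network produced non-finite outputs")
  }
  term_joint <- mean(t_joint)
  term_marginal <- logmeanexp(t_shuf)
  structure(list(value = term_joint - term_marginal,
                 term_joint = term_joint, term_marginal = term_marginal,
                 n_samples = joint$n),
            class = "mi_estimate")
}

# Ascent gradient of the DV objective w.r.t. critic parameters (and
# optionally the inputs), plus the estimate itself, from one fused pass.
dv_gradients <- function(T_net, joint, shuffled, want_inputs = FALSE) {
  X1 <- cbind(joint$h1, joint$h2)
  X2 <- cbind(shuffled$h1, shuffled$h2)
  ps <- cpp_dv_pass(T_net$W, T_net$b, X1, X2, want_inputs)
  grads <- list()
  for (l in seq_along(T_net$W)) {
    grads[[paste0("W", l)]] <- ps$dW[[l]]
    grads[[paste0("b", l)]] <- drop(ps$db[[l]])
  }
  est <- structure(list(value = ps$value, term_joint = ps$term_joint,
                        term_marginal = ps$term_marginal,
                        n_samples = joint$n),
                   class = "mi_estimate")
  out <- list(grads = grads, estimate = est)
  if (want_inputs) {
    d1 <- ncol(joint$h1)
    dh1 <- ps$dX1[, seq_len(d1), drop = FALSE] +
      ps$dX2[, seq_len(d1), drop = FALSE]
    dh2 <- ps$dX1[, -seq_len(d1), drop = FALSE]
    # shuffled rows carry h2[perm]; scatter their gradient back to the source
    perm <- attr(shuffled, "perm")
    dh2_sh <- ps$dX2[, -seq_len(d1), drop = FALSE]
    dh2[perm, ] <- dh2[perm, , drop = FALSE] + dh2_sh
    out$dh1 <- dh1
    out$dh2 <- dh2
  }
  out
}

sm_flatten <- function(T_net) {
  out <- list()
  for (l in seq_along(T_net$W)) {
    out[[paste0("W", l)]] <- T_net$W[[l]]
    out[[paste0("b", l)]] <- T_net$b[[l]]
  }
  out
}

sm_unflatten <- function(T_net, flat) {
  for (l in seq_along(T_net$W)) {
    T_net$W[[l]] <- flat[[paste0("W", l)]]
    T_net$b[[l]] <- flat[[paste0("b", l)]]
  }
  T_net
}

#' One ascent step of the critic
#'
#' Performs a single adaptive-moment gradient ascent step on the
#' Donsker-Varadhan objective with respect to the critic parameters and
#' returns the pre-step estimate.  Non-finite gradients skip the step.
#'
#' @param T_net A [init_statistics_network()] object.
#' @param joint,shuffled Paired samples as in [dv_estimate()].
#' @param opt_state Optimizer state from [adam_init()] (created on first use
#'   when `NULL`).
#' @param lr Learning rate.
#' @return List with updated `T_net`, `opt_state`, and `estimate`.
#' @export
sm_update <- function(T_net, joint, shuffled, opt_state = NULL, lr = 1e-3) {
  dg <- dv_gradients(T_net, joint, shuffled)
  est <- dg$estimate
  if (!is.finite(est$value)) stop("statistics network produced non-finite outputs")
  flat <- sm_flatten(T_net)
  if (is.null(opt_state)) opt_state <- adam_init(flat)
  gr <- dg$grads
  finite <- all(vapply(gr, function(g) all(is.finite(g)), logical(1)))
  if (finite) {
    # ascent: feed the negated gradient to the (descending) optimizer
    neg <- lapply(gr, function(g) -g)
    upd <- adam_step(opt_state, flat, neg, lr)
    T_net <- sm_unflatten(T_net, upd$params)
    opt_state <- upd$state
  }
  list(T_net = T_net, opt_state = opt_state, estimate = est)
}

#' Fit a MINE estimator on a fixed paired dataset
#'
#' Convenience routine for standalone MI estimation: repeatedly subsamples
#' the dataset, shuffles within the subsample, and ascends the
#' Donsker-Varadhan objective; returns the trained critic and the final
#' estimate on the full dataset (fresh shuffle).
#'
#' @param x,y Numeric matrices (n x dx, n x dy) of paired observations.
#' @param hidden Hidden widths of the critic.
#' @param iters Number of ascent iterations.
#' @param minibatch Subsample size per iteration (capped at n).
#' @param lr Learning rate.
#' @param seed Integer seed.
#' @return List with `T_net`, `estimate` (an `mi_estimate`), and the
#'   per-iteration estimate trace.
#' @export
train_mine <- function(x, y, hidden = c(64, 64), iters = 300,
                       minibatch = 512, lr = 1e-3, seed = 1L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 4)
  n <- nrow(x)
  minibatch <- min(minibatch, n)
  withr::with_seed(as.integer(seed), {
    T_net <- init_statistics_network(ncol(x) + ncol(y), hidden)
    opt <- NULL
    trace <- numeric(iters)
    for (i in seq_len(iters)) {
      idx <- sample.int(n, minibatch)
      joint <- structure(list(h1 = x[idx, , drop = FALSE],
                              h2 = y[idx, , drop = FALSE], n = minibatch),
                         class = "paired_samples")
      shuf <- shuffle_pairs(joint, sample.int(.Machine$integer.max, 1))
      res <- sm_update(T_net, joint, shuf, opt, lr)
      T_net <- res$T_net
      opt <- res$opt_state
      trace[i] <- res$estimate$value
    }
    full <- structure(list(h1 = x, h2 = y, n = n), class = "paired_samples")
    shuf <- shuffle_pairs(full, sample.int(.Machine$integer.max, 1))
    list(T_net = T_net, estimate = dv_estimate(T_net, full, shuf),
         trace = trace)
  })
}
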