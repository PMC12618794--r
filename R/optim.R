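#' Adaptive-moment (Adam) optimizer state
#'
#' @param params Named list of numeric arrays (the parameters to optimize).
#' @return Optimizer state list.
#' @export
adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

#' One Adam descent step
#'
#' Standard bias-corrected adaptive-moment update applied element-wise to
#' every parameter array; gradients are for the loss being *minimized*.
#'
#' @param state State from [adam_init()].
#' @param params Named list of parameter arrays.
#' @param grads Matching named list of gradients.
#' @param lr Learning rate.
#' @param beta1,beta2 Moment decay rates.
#' @param eps Numerical floor.
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(state, params, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Clip a gradient list to a maximum global norm
#'
#' Rescales all gradients jointly so the Euclidean norm of the concatenated
#' gradient does not exceed `max_norm`; used for BPTT stability.
#'
#' @param grads Named list of gradient arrays.
#' @param max_norm Maximum global norm.
#' @return Rescaled gradient list.
#' @export
clip_global_norm <- function(grads, max_norm = 10) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}
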