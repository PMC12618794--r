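#' Working-memory task loss
#'
#' Mean squared error between outputs and +/-1 targets over the two memory
#' bits, restricted to post-transient steps:
#' \eqn{L_{task} = \frac{1}{2L'} \sum_{t > transient} \sum_{j=1}^{2}
#' (y_t^{(j)} - \hat y_t^{(j)})^2}.
#'
#' @param y Output trace, L x 2.
#' @param targets Target trace, L x 2.
#' @param transient Leading steps excluded from the loss.
#' @return Scalar loss.
#' @export
wm_task_loss <- function(y, targets, transient) {
  stopifnot(nrow(y) == nrow(targets), ncol(y) == 2, ncol(targets) == 2,
            transient < nrow(y))
  keep <- (transient + 1):nrow(y)
  sum((y[keep, , drop = FALSE] - targets[keep, , drop = FALSE])^2) /
    (2 * length(keep))
}

#' Separation task loss
#'
#' \eqn{L_{task} = \frac{1}{2L} \sum_t (\|y^{(1)}_t - x^{(1)}_t\|^2 +
#' \|y^{(2)}_t - x^{(2)}_t\|^2)} where \eqn{x^{(1)}} and \eqn{x^{(2)}} are
#' the standardized Lorenz and Roessler components.
#'
#' @param y1,y2 Output traces, L x 3.
#' @param target_lorenz,target_rossler Target components, L x 3.
#' @return Scalar loss.
#' @export
separation_task_loss <- function(y1, y2, target_lorenz, target_rossler) {
  stopifnot(all(dim(y1) == dim(target_lorenz)),
            all(dim(y2) == dim(target_rossler)))
  (sum((y1 - target_lorenz)^2) + sum((y2 - target_rossler)^2)) /
    (2 * nrow(y1))
}

#' L2 weight penalty
#'
#' \eqn{L_{reg} = \frac{1}{2} \sum_{w} w^2} over all weight matrices of the
#' main model (recurrent, input, gate, and readout weights); biases are
#' excluded.
#'
#' @param params Named list of parameter arrays; entries whose names start
#'   with `W` or `U` count as weights.
#' @return Scalar penalty.
#' @export
l2_penalty <- function(params) {
  nms <- grep("^(W|U)", names(params), value = TRUE)
  sum(vapply(params[nms], function(w) sum(w^2), numeric(1))) / 2
}

#' Total training loss of the main model
#'
#' \eqn{L = L_{task} + \lambda_{reg} L_{reg} + \lambda_I \hat I}.
#'
#' @param task Task loss.
#' @param reg L2 penalty.
#' @param mi Estimated mutual information (nats).
#' @param lambda_reg,lambda_I Loss weights.
#' @return List (class `loss_breakdown`) with `L_task`, `L_reg`, `I_hat`,
#'   `total`.
#' @export
total_loss <- function(task, reg, mi, lambda_reg, lambda_I) {
  structure(list(L_task = task, L_reg = reg, I_hat = mi,
                 total = task + lambda_reg * reg + lambda_I * mi),
            class = "loss_breakdown")
}
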