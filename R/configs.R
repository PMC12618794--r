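#' Shipped training profiles
#'
#' `full` mirrors the full benchmark conditions (N = 64 working-memory / 128
#' separation networks, batch 32, 128x128 critic, 2,000-step sequences);
#' `fast` is the desk-scale profile used by the test suite and the
#' acceptance script (smaller network, batch, and iteration budget chosen
#' so one trial runs in about a minute on one CPU while preserving the
#' qualitative contrasts).
#'
#' @param task `"wm"` or `"sep"`.
#' @param profile `"fast"` or `"full"`.
#' @param ... Overrides passed to [training_config()].
#' @return A [training_config()].
#' @export
midiff_profile <- function(task = c("wm", "sep"),
                           profile = c("fast", "full"), ...) {
  task <- match.arg(task)
  profile <- match.arg(profile)
  base <- if (task == "wm") {
    if (profile == "fast") {
      list(task = "wm", N = 32L, n_batch = 8L, L_train = 1000L,
           transient_train = 500L, L_eval = 2000L, transient_eval = 1000L,
           n_eval = 8L, lambda_I = 0.15, mm_iterations = 800L,
           sm_hidden = c(64L, 64L), sm_minibatch = 512L,
           mi_minibatch = 4000L, lr_mm = 2e-3, lr_sm = 2e-3,
           eval_every = 20L)
    } else {
      list(task = "wm", N = 64L, n_batch = 32L, mm_iterations = 2000L)
    }
  } else {
    if (profile == "fast") {
      list(task = "sep", N = 32L, n_batch = 4L, L_train = 300L,
           L_eval = 300L, n_eval = 4L, mm_iterations = 120L,
           sm_hidden = c(64L, 64L), sm_minibatch = 256L,
           lr_mm = 3e-3, lr_sm = 2e-3, eval_every = 10L)
    } else {
      list(task = "sep", N = 128L, n_batch = 32L, L_train = 500L,
           L_eval = 500L, mm_iterations = 3000L)
    }
  }
  args <- utils::modifyList(base, list(...))
  do.call(training_config, args)
}

#' Read a training configuration from a YAML file
#'
#' Keys mirror the arguments of [training_config()]; nested `lorenz` /
#' `rossler` blocks (fields of [chaotic_system_spec()]) configure the
#' separation task's systems.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file.
#' @return A [training_config()].
#' @export
load_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  for (sys in c("lorenz", "rossler")) {
    if (!is.null(raw[[sys]])) {
      raw[[sys]] <- do.call(chaotic_system_spec,
                            c(list(name = sys), raw[[sys]]))
    }
  }
  if ("sm_hidden" %in% names(raw)) raw$sm_hidden <- as.integer(raw$sm_hidden)
  args <- utils::modifyList(raw, list(...))
  do.call(training_config, args)
}
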