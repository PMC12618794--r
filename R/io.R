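config_hash <- function(obj) {
  # order-stable structural fingerprint; avoids an external digest dependency
  s <- paste(deparse(obj[order(names(obj))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

#' Export a generated task batch to a columnar archive
#'
#' Writes one directory per batch: long-format CSVs of inputs and targets
#' (columns `seq`, `t`, `channel`, `value`) plus a JSON manifest carrying
#' the seed and a structural hash of the generating configuration.
#'
#' @param batch A batch from [generate_wm_batch()] or
#'   [generate_separation_batch()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_batch <- function(batch, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- function(a) {
    d <- dim(a)
    data.frame(seq = rep(seq_len(d[3]), each = d[1] * d[2]),
               t = rep(seq_len(d[1]), times = d[2] * d[3]),
               channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               value = as.vector(a))
  }
  if (!is.null(batch$inputs)) {        # working-memory batch
    utils::write.csv(long(batch$inputs), file.path(dir, "inputs.csv"),
                     row.names = FALSE)
    utils::write.csv(long(batch$targets), file.path(dir, "targets.csv"),
                     row.names = FALSE)
    cfg <- batch$cfg
  } else {                             # separation batch
    utils::write.csv(long(batch$mixed_input), file.path(dir, "inputs.csv"),
                     row.names = FALSE)
    utils::write.csv(long(batch$target_lorenz),
                     file.path(dir, "target_lorenz.csv"), row.names = FALSE)
    utils::write.csv(long(batch$target_rossler),
                     file.path(dir, "target_rossler.csv"), row.names = FALSE)
    cfg <- NULL
  }
  jsonlite::write_json(list(seed = batch$seed,
                            config_hash = if (is.null(cfg)) NA else
                              config_hash(unclass(cfg))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Write and read model parameter checkpoints
#'
#' Checkpoints are portable JSON archives: every parameter array with its
#' dimensions, plus a manifest (architecture, network size, seed, and a
#' structural hash of the configuration).
#'
#' @param params MM parameters ([init_leaky_params()]/[init_gru_params()]).
#' @param readout Readout parameters ([init_readout()]).
#' @param path Output file path.
#' @param cfg Optional [training_config()] for the manifest.
#' @param T_net Optional critic ([init_statistics_network()]).
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(params, readout, path, cfg = NULL,
                             T_net = NULL) {
  arch <- if (inherits(params, "leaky_params")) "leaky" else "gru"
  n_units <- if (arch == "leaky") nrow(params$Wrec) else nrow(params$Uz)
  enc <- function(lst) {
    lapply(lst, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else if (is.numeric(p)) list(dim = length(p), data = as.vector(p))
      else p
    })
  }
  out <- list(manifest = list(architecture = arch, N = n_units,
                              seed = if (is.null(cfg)) NA else cfg$seed,
                              config_hash = if (is.null(cfg)) NA else
                                config_hash(unclass(cfg))),
              params = enc(unclass(params)),
              readout = enc(unclass(readout)))
  if (!is.null(T_net)) {
    out$critic <- list(hidden = T_net$hidden, W = enc(T_net$W),
                       b = enc(T_net$b))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @return For `read_checkpoint`: a list with `manifest`, `params`,
#'   `readout` (and `critic` when present), arrays restored to their
#'   original shapes.
#' @export
read_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  dec <- function(lst) {
    lapply(lst, function(p) {
      if (is.list(p) && !is.null(p$data)) {
        if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
        else as.numeric(p$data)
      } else p
    })
  }
  out <- list(manifest = raw$manifest, params = dec(raw$params),
              readout = dec(raw$readout))
  cls <- if (identical(raw$manifest$architecture, "leaky")) "leaky_params"
         else "gru_params"
  class(out$params) <- cls
  class(out$readout) <- "readout_params"
  if (!is.null(raw$critic)) {
    out$critic <- list(hidden = raw$critic$hidden, W = dec(raw$critic$W),
                       b = dec(raw$critic$b))
  }
  out
}
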