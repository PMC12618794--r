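# Shared fixtures and independent oracles used across test files.

# Brute-force Newman modularity: literal double loop over ordered pairs.
brute_modularity <- function(A, partition) {
  n <- nrow(A)
  a_total <- sum(A) / 2
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (partition[i] == partition[j]) {
        q <- q + A[i, j] - k[i] * k[j] / (2 * a_total)
      }
    }
  }
  q / (2 * a_total)
}

# Random symmetric non-negative graph with zero diagonal.
random_graph <- function(n, density = 0.3) {
  A <- matrix(0, n, n)
  upper <- which(upper.tri(A))
  on <- upper[stats::runif(length(upper)) < density]
  A[on] <- stats::runif(length(on))
  A <- A + t(A)
  diag(A) <- 0
  A
}

# All partitions of seq_len(n) as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, maxl) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) {
      grow(c(labels, l), max(maxl, l))
    }
  }
  grow(integer(0), 0L)
  out
}

# Two disconnected unit-weight cliques of size k each.
two_cliques <- function(k) {
  A <- matrix(0, 2 * k, 2 * k)
  A[1:k, 1:k] <- 1
  A[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(A) <- 0
  A
}

# Tiny training configuration for schedule/determinism tests.
tiny_wm_cfg <- function(...) {
  midiff_profile("wm", "fast", N = 8L, n_batch = 2L, L_train = 60L,
                 transient_train = 20L, L_eval = 80L, transient_eval = 20L,
                 n_eval = 2L, mm_iterations = 3L, sm_pretrain = 4L,
                 sm_per_mm = 2L, sm_hidden = c(8L, 8L), sm_minibatch = 32L,
                 eval_every = 1L, ...)
}
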