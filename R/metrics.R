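#' Fixed half/half neuron group assignment
#'
#' The recurrent layer is split into two equal, contiguous groups: group 1 is
#' the first `N/2` neuron indices, group 2 the rest.  This partition is fixed
#' before training and never revisited; all modularity and separability
#' metrics are evaluated against it.
#'
#' @param n Number of neurons (must be even).
#' @return Integer vector of length `n` with values 1 and 2.
#' @export
group_assignment <- function(n) {
  stopifnot(length(n) == 1L, n >= 2L, n %% 2L == 0L)
  rep(1:2, each = n %/% 2L)
}

check_weighted_graph <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(!is.finite(A))) stop("adjacency matrix contains non-finite entries")
  if (any(A < 0)) stop("adjacency matrix must be non-negative")
  if (max(abs(A - t(A))) > 1e-10) stop("adjacency matrix must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency matrix must have zero diagonal")
  invisible(A)
}

#' Newman modularity of a weighted graph under a fixed partition
#'
#' Computes \eqn{Q = \frac{1}{2A_{tot}} \sum_{ij} (A_{ij} - k_i k_j / 2A_{tot})
#' \delta(s_i, s_j)} where \eqn{k_i} is the weighted degree and
#' \eqn{A_{tot} = \frac{1}{2}\sum_{ij} A_{ij}}.  The sum runs over all ordered
#' pairs including \eqn{i = j} in the degree-product term (the diagonal of
#' `A` itself is required to be zero).
#'
#' @param A Symmetric non-negative adjacency matrix with zero diagonal.
#' @param partition Integer vector of group labels, one per node.
#' @return Modularity Q, a scalar in \[-1, 1\].
#' @export
newman_modularity <- function(A, partition) {
  check_weighted_graph(A)
  stopifnot(length(partition) == nrow(A))
  a_total <- sum(A) / 2
  if (a_total <= 0) stop("total edge weight is zero; modularity undefined")
  k <- rowSums(A)
  same <- outer(partition, partition, "==")
  sum((A - outer(k, k) / (2 * a_total)) * same) / (2 * a_total)
}

#' Functional connectivity graph from neural activity
#'
#' Builds the absolute pairwise Pearson correlation matrix of the columns of
#' an activity array and zeroes its diagonal.  Columns with zero variance
#' (silent neurons) get all their correlations set to 0; their indices are
#' attached as the `"zero_variance"` attribute.
#'
#' @param activity Numeric matrix, time steps x neurons.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
correlation_graph <- function(activity) {
  stopifnot(is.matrix(activity), nrow(activity) >= 2)
  sds <- apply(activity, 2, stats::sd)
  dead <- unname(which(sds == 0 | !is.finite(sds)))
  A <- suppressWarnings(abs(stats::cor(activity)))
  if (length(dead) > 0) {
    A[dead, ] <- 0
    A[, dead] <- 0
  }
  A[!is.finite(A)] <- 0
  diag(A) <- 0
  A <- (A + t(A)) / 2  # exact symmetry against floating-point asymmetry
  dimnames(A) <- NULL
  attr(A, "zero_variance") <- dead
  A
}

#' Structural connectivity graph from a recurrent weight matrix
#'
#' Symmetrizes a (generally asymmetric) weight matrix as
#' \eqn{A = |W| + |W^T|} and removes the diagonal, so that self-connections
#' never contribute to structural modularity.
#'
#' @param W Square numeric weight matrix.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
structural_graph <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  A <- abs(W) + t(abs(W))
  diag(A) <- 0
  A
}

d_contrast <- function(m1, m2, groups) {
  # shared core of the D indices: |sum_i (-1)^{s_i} (|m2_i| - |m1_i|)| / sum(|m1|+|m2|)
  sgn <- (-1)^groups
  num <- sum(sgn * (abs(m2) - abs(m1)))
  den <- sum(abs(m1) + abs(m2))
  if (den <= 0) stop("all weights are zero; separability index undefined")
  abs(num / den)
}

#' Output separability index
#'
#' Measures how exclusively each neuron group projects to one of the two
#' output channels, as a normalized contrast of absolute output weights.
#' 1 means each group drives exactly one output, 0 means both groups
#' contribute equally to both.
#'
#' @param W_y1,W_y2 Output weight matrices (M x N) of the two readouts.
#' @param groups Group labels from [group_assignment()].
#' @return Scalar in \[0, 1\].
#' @export
d_out <- function(W_y1, W_y2, groups) {
  stopifnot(ncol(W_y1) == length(groups), ncol(W_y2) == length(groups))
  sgn <- matrix((-1)^groups, nrow = nrow(W_y1), ncol = length(groups), byrow = TRUE)
  num <- sum(sgn * (abs(W_y2) - abs(W_y1)))
  den <- sum(abs(W_y1) + abs(W_y2))
  if (den <= 0) stop("all output weights are zero; D_out undefined")
  abs(num / den)
}

#' Input separability index (working-memory task only)
#'
#' The four input channels are ordered (ON1, OFF1, ON2, OFF2); channels
#' 1:2 address memory bit 1 and channels 3:4 memory bit 2.  D_in contrasts
#' the absolute input weights each group receives from the two bits.
#'
#' @param W_in Input weight matrix, N x 4.
#' @param groups Group labels from [group_assignment()].
#' @return Scalar in \[0, 1\].
#' @export
d_in <- function(W_in, groups) {
  stopifnot(ncol(W_in) == 4, nrow(W_in) == length(groups))
  bit1 <- abs(W_in[, 1]) + abs(W_in[, 2])
  bit2 <- abs(W_in[, 3]) + abs(W_in[, 4])
  d_contrast(bit2, bit1, groups)  # (-1)^s (|bit1| - |bit2|) per the index definition
}

#' Neuron-output correlation summaries
#'
#' For each neuron, the mean absolute Pearson correlation between its
#' activity trace and the M components of each of the two outputs:
#' \eqn{c_i^{(j)} = \frac{1}{M} \sum_k |corr(a_i, y^{(j)}_k)|}.
#' Zero-variance series contribute 0.
#'
#' @param activity Numeric matrix, time steps x neurons.
#' @param y1,y2 Output traces, time steps x M.
#' @return N x 2 matrix of correlation summaries.
#' @export
neuron_output_correlations <- function(activity, y1, y2) {
  stopifnot(is.matrix(activity), nrow(activity) >= 2,
            nrow(y1) == nrow(activity), nrow(y2) == nrow(activity))
  one <- function(y) {
    cc <- suppressWarnings(abs(stats::cor(activity, y)))
    cc[!is.finite(cc)] <- 0
    rowMeans(cc)
  }
  cbind(one(as.matrix(y1)), one(as.matrix(y2)))
}

#' Correlation separability index
#'
#' Normalized contrast of the neuron-output correlation summaries
#' (see [neuron_output_correlations()]) between the two groups; the
#' functional counterpart of [d_out()].
#'
#' @param c_mat N x 2 matrix of correlation summaries.
#' @param groups Group labels from [group_assignment()].
#' @return Scalar in \[0, 1\].
#' @export
d_cor <- function(c_mat, groups) {
  stopifnot(ncol(c_mat) == 2, nrow(c_mat) == length(groups))
  d_contrast(c_mat[, 1], c_mat[, 2], groups)
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_t (s_t - \hat{s}_t)^2 / \sum_t (s_t - \bar{s})^2}.
#'
#' @param target Observed series (the signal to reconstruct).
#' @param pred Predicted series.
#' @return Scalar (1 for a perfect fit, 0 for predicting the mean).
#' @export
r_squared <- function(target, pred) {
  stopifnot(length(target) == length(pred), length(target) >= 2)
  ss_tot <- sum((target - mean(target))^2)
  if (ss_tot <= 0) stop("target series is constant; R^2 undefined")
  1 - sum((target - pred)^2) / ss_tot
}

#' Fraction of correct working-memory output states
#'
#' A (step, bit) pair is correct when the sign of the output matches the
#' sign of the +/-1 target; an exactly zero output never counts as correct.
#' Only post-transient steps are evaluated.
#'
#' @param y Output trace, L x 2.
#' @param targets Target trace, L x 2 with entries in \{-1, +1\}.
#' @param transient Number of leading steps to exclude.
#' @return Fraction in \[0, 1\].
#' @export
wm_correct_fraction <- function(y, targets, transient) {
  stopifnot(nrow(y) == nrow(targets), ncol(y) == 2, ncol(targets) == 2,
            transient < nrow(y))
  keep <- (transient + 1):nrow(y)
  mean(sign(y[keep, , drop = FALSE]) == targets[keep, , drop = FALSE])
}

#' Working-memory success criterion
#'
#' Success requires the correct output state on strictly more than 90% of
#' post-transient (step, bit) pairs.
#'
#' @inheritParams wm_correct_fraction
#' @param threshold Required fraction (strict inequality), default 0.9.
#' @return Logical.
#' @export
wm_success <- function(y, targets, transient, threshold = 0.9) {
  wm_correct_fraction(y, targets, transient) > threshold
}

#' Greedy community detection on a weighted graph
#'
#' Agglomerative (fast greedy) modularity maximization, delegated to
#' `igraph::cluster_fast_greedy` on the weighted undirected graph.
#'
#' @param A Symmetric non-negative adjacency matrix with zero diagonal.
#' @return Integer membership vector.
#' @export
detect_communities <- function(A) {
  check_weighted_graph(A)
  if (sum(A) <= 0) stop("graph has no edges; community detection undefined")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
}

#' Normalized mutual information between two partitions
#'
#' \eqn{I_n = I(G;C) / (\frac{1}{2}[H(G) + H(C)])}, with entropies and MI
#' computed from the empirical joint label counts.  1 for identical
#' partitions (up to relabeling), 0 for independent ones.
#'
#' @param g,c Integer label vectors over the same node set.
#' @return Scalar in \[0, 1\].
#' @export
normalized_mi <- function(g, c) {
  stopifnot(length(g) == length(c), length(g) >= 1)
  n <- length(g)
  joint <- table(g, c) / n
  pg <- rowSums(joint)
  pc <- colSums(joint)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hg <- ent(pg)
  hc <- ent(pc)
  if (hg == 0 || hc == 0) {
    stop("a partition has a single community; normalized MI undefined")
  }
  pij <- joint[joint > 0]
  outer_p <- outer(pg, pc)[joint > 0]
  i_gc <- sum(pij * log(pij / outer_p))
  i_gc / ((hg + hc) / 2)
}
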