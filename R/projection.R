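## Principal Projection: low-rank attribute operators from task-head
## weights via SVD, embedding projection, operator alignment, and
## attribute-contribution reporting.

#' Build a low-rank projection operator from task heads
#'
#' Concatenates the head weight matrices column-wise (raw, no centering),
#' computes the singular-value decomposition `W = U S V^T`, and keeps the
#' smallest leading set of singular directions whose squared singular
#' values first reach a fraction `lambda` of the total squared sum
#' (default 95%). The operator is the corresponding block of
#' left-singular columns.
#'
#' @param task_heads non-empty list of heads, each with a `D x n_classes`
#'   matrix `W` (bias vectors are not part of the decomposition).
#' @param lambda retained fraction of total squared singular values,
#'   in (0, 1].
#' @param attribute optional attribute name recorded on the operator.
#' @return List of class `projection_operator`: `U` (D x D_tilde with
#'   orthonormal columns), `rank`, `retained_energy`, `singular_values`,
#'   `lambda`, `attribute`, `source_tasks`.
#' @export
low_rank_operator <- function(task_heads, lambda = 0.95, attribute = NA_character_) {
  if (length(task_heads) == 0) stop("empty head list", call. = FALSE)
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]", call. = FALSE)
  Ws <- lapply(task_heads, function(h) if (is.list(h)) h$W else h)
  D <- nrow(Ws[[1]])
  if (any(vapply(Ws, nrow, 0L) != D))
    stop("all heads must share the embedding dimension", call. = FALSE)
  Wcat <- do.call(cbind, Ws)
  sv <- svd(Wcat)
  s2 <- sv$d^2
  total <- sum(s2)
  cum <- cumsum(s2)
  rank <- which(cum >= lambda * total - 1e-12)[1]
  op <- list(U = sv$u[, seq_len(rank), drop = FALSE],
             rank = rank,
             retained_energy = cum[rank] / total,
             singular_values = sv$d,
             lambda = lambda,
             attribute = attribute,
             source_tasks = names(task_heads) %||% rep(NA_character_, length(task_heads)))
  class(op) <- "projection_operator"
  op
}

#' Project embeddings with a low-rank operator
#'
#' `z_tilde = U^T z` per trace, applied before any 2-D reduction.
#'
#' @param embeddings N x D matrix or `embedding_set`.
#' @param op a `projection_operator`.
#' @return N x D_tilde matrix of projected embeddings.
#' @export
project_embeddings <- function(embeddings, op) {
  if (inherits(embeddings, "embedding_set")) embeddings <- embeddings$z0
  X <- as.matrix(embeddings)
  if (ncol(X) != nrow(op$U))
    stop("embedding dimension does not match the operator", call. = FALSE)
  X %*% op$U
}

#' Alignment score between two projection operators
#'
#' The spectral norm `phi = || U1^T U2 ||_2` (largest singular value of
#' the product). Orthogonal column spans give 0; operators equal up to a
#' unitary rotation give 1; in general `0 <= phi <= 1`.
#'
#' @param op1,op2 `projection_operator`s over the same embedding
#'   dimension.
#' @return Scalar alignment in [0, 1].
#' @export
alignment_score <- function(op1, op2) {
  U1 <- if (inherits(op1, "projection_operator")) op1$U else op1
  U2 <- if (inherits(op2, "projection_operator")) op2$U else op2
  if (nrow(U1) != nrow(U2))
    stop("operators must share the embedding dimension", call. = FALSE)
  M <- crossprod(U1, U2)
  max(svd(M, nu = 0, nv = 0)$d)
}

#' Build per-attribute projection operators from pre-trained heads
#'
#' Groups the task heads of a weight set by attribute and builds one
#' low-rank operator per attribute.
#'
#' @param weights pre-trained weight list holding `heads`.
#' @param tasks the matching task roster.
#' @param lambda retained energy fraction.
#' @return Named list of `projection_operator`s, one per attribute group.
#' @export
attribute_operators <- function(weights, tasks = task_roster(), lambda = 0.95) {
  groups <- split(names(tasks), vapply(tasks, function(t) t$attribute_group, ""))
  lapply(groups, function(nms) {
    heads <- weights$heads[nms]
    names(heads) <- nms
    low_rank_operator(heads, lambda = lambda,
                      attribute = tasks[[nms[1]]]$attribute_group)
  })
}

#' Attribute contributions to a classifier head
#'
#' Builds the low-rank operator of the (fine-tuned) classifier head and
#' reports its alignment `phi` with each attribute operator, plus the
#' alignments normalized to fractions summing to 1. If the head is
#' orthogonal to every attribute the fractions are undefined and are
#' reported as uniform with a warning.
#'
#' @param classifier_head list with `W` (D x n_classes) and `b`.
#' @param attribute_ops named list of attribute `projection_operator`s.
#' @param lambda retained energy for the classifier operator.
#' @return data.frame with columns `attribute`, `phi`, `fraction`.
#' @export
attribute_contributions <- function(classifier_head, attribute_ops, lambda = 0.95) {
  op_head <- low_rank_operator(list(head = classifier_head), lambda = lambda)
  phi <- vapply(attribute_ops, function(op) alignment_score(op_head, op), 0)
  if (sum(phi) < 1e-12) {
    warning("classifier head is orthogonal to every attribute; fractions reported as uniform")
    frac <- rep(1 / length(phi), length(phi))
  } else {
    frac <- phi / sum(phi)
  }
  data.frame(attribute = names(attribute_ops), phi = phi, fraction = frac,
             row.names = NULL, stringsAsFactors = FALSE)
}
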