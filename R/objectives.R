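# Self-supervised objectives over masked molecular graphs.
#
# AttrMask: a linear head over the atom-type vocabulary on the embeddings
# of masked nodes, mean cross-entropy on masked positions only.
# GraphMAE-style: masked-node embeddings are re-masked with a learned
# decoder mask vector, one additional GIN layer decodes, and a linear head
# reconstructs the atom type; loss is cross-entropy by default (atom types
# are categorical) with a scaled-cosine variant behind a switch.

N_ATOM_CLASSES <- 118L  # prediction targets are real elements, never the mask token

#' Initialize AttrMask head parameters
#' @param hidden_dim Encoder embedding width.
#' @return List with `W` (hidden_dim x 118) and `b` (118).
#' @export
init_attrmask_head <- function(hidden_dim) {
  list(W = glorot(hidden_dim, N_ATOM_CLASSES), b = numeric(N_ATOM_CLASSES))
}

#' Initialize GraphMAE decoder parameters
#' @param hidden_dim Encoder embedding width.
#' @return List with `mask_vec` (learned re-mask embedding), `layer` (one
#'   GIN decoder layer) and the linear reconstruction head `W`, `b`.
#' @export
init_graphmae_decoder <- function(hidden_dim) {
  list(mask_vec = stats::runif(hidden_dim, -0.05, 0.05),
       layer = gin_layer_params(hidden_dim),
       W = glorot(hidden_dim, N_ATOM_CLASSES), b = numeric(N_ATOM_CLASSES))
}

# Numerically stable softmax cross-entropy with accuracy; returns gradient
# w.r.t. logits already divided by the number of rows (mean loss).
softmax_ce <- function(logits, targets) {
  m <- nrow(logits)
  shifted <- logits - apply(logits, 1, max)
  logZ <- log(rowSums(exp(shifted)))
  logp <- shifted - logZ
  idx <- cbind(seq_len(m), targets)
  loss <- -mean(logp[idx])
  probs <- exp(logp)
  acc <- mean(max.col(logits, ties.method = "first") == targets)
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, accuracy = acc, dlogits = dlogits / m)
}

# Scaled-cosine reconstruction error against one-hot targets (GraphMAE's
# original loss for continuous features), gamma = 2.
scaled_cosine_loss <- function(pred, targets, gamma = 2) {
  m <- nrow(pred)
  tnorm <- 1  # one-hot targets have unit norm
  pnorm <- sqrt(rowSums(pred^2)) + 1e-12
  tdot <- pred[cbind(seq_len(m), targets)]
  cosine <- tdot / (pnorm * tnorm)
  loss <- mean((1 - cosine)^gamma)
  acc <- mean(max.col(pred, ties.method = "first") == targets)
  # cos = tdot / pnorm ; dcos/dpred_j = t_j/pnorm - tdot*p_j/pnorm^3
  dcos <- -gamma * (1 - cosine)^(gamma - 1) / m
  dpred <- -sweep(pred, 1, dcos * tdot / pnorm^3, "*")
  dpred[cbind(seq_len(m), targets)] <- dpred[cbind(seq_len(m), targets)] +
    dcos / pnorm
  list(loss = loss, accuracy = acc, dpred = dpred)
}

#' AttrMask objective: masked-atom type prediction
#'
#' Applies a linear classification head over the 118 element classes to the
#' embeddings of masked nodes only; loss is the mean cross-entropy over
#' masked nodes and accuracy the argmax match rate.
#'
#' @param ne Node embeddings (matrix `n_nodes x hidden_dim`), e.g. from
#'   [encode()] on the corrupted graph.
#' @param plan The `mask_plan` used to corrupt the graph (indices relative
#'   to `ne` rows).
#' @param targets Integer vector of original atom-type indices at the
#'   masked positions (as returned by [apply_mask()]), aligned with
#'   `plan$masked_indices`.
#' @param head Head parameters from [init_attrmask_head()].
#' @return Object of class `pretrain_batch_result`: `loss`,
#'   `masked_atom_accuracy`, `n_masked`, plus a `backward()` closure
#'   returning `list(dne, dhead)` for training.
#' @export
attrmask_objective <- function(ne, plan, targets, head) {
  idx <- plan$masked_indices
  if (length(idx) == 0L) stop("no masked nodes: the objective is undefined")
  if (length(targets) != length(idx)) {
    stop("targets must cover exactly the masked indices")
  }
  targets <- as.integer(targets)
  if (any(targets < 1L | targets > N_ATOM_CLASSES)) {
    stop("target atom-type index outside 1..", N_ATOM_CLASSES)
  }
  hm <- unclass(ne)[idx, , drop = FALSE]
  logits <- sweep(hm %*% head$W, 2, head$b, "+")
  ce <- softmax_ce(logits, targets)
  backward <- function() {
    dW <- crossprod(hm, ce$dlogits)
    db <- colSums(ce$dlogits)
    dhm <- tcrossprod(ce$dlogits, head$W)
    dne <- matrix(0, nrow(ne), ncol(ne))
    dne[idx, ] <- dhm
    list(dne = dne, dhead = list(W = dW, b = db))
  }
  structure(list(loss = ce$loss, masked_atom_accuracy = ce$accuracy,
                 n_masked = length(idx), backward = backward),
            class = "pretrain_batch_result")
}

#' GraphMAE-style objective: re-mask, decode, reconstruct atom types
#'
#' The masked nodes' encoder embeddings are replaced by a learned decoder
#' mask vector (re-masking), one additional GIN layer propagates over the
#' same edges, and a linear head reconstructs the atom type of the masked
#' nodes. Loss is mean cross-entropy on masked nodes (default) or the
#' scaled-cosine error against one-hot targets (`loss_type = "sce"`).
#'
#' @param ne Node embeddings of the corrupted graph (matrix).
#' @param gt The corrupted `graph_tensors` (provides the edges the decoder
#'   layer propagates over).
#' @param plan The `mask_plan`.
#' @param targets Original atom-type indices at masked positions.
#' @param decoder Parameters from [init_graphmae_decoder()].
#' @param loss_type "ce" (default) or "sce".
#' @return A `pretrain_batch_result` (see [attrmask_objective()]); its
#'   `backward()` returns `list(dne, ddecoder)`.
#' @export
graphmae_objective <- function(ne, gt, plan, targets, decoder,
                               loss_type = c("ce", "sce")) {
  loss_type <- match.arg(loss_type)
  idx <- plan$masked_indices
  if (length(idx) == 0L) stop("no masked nodes: the objective is undefined")
  if (length(targets) != length(idx)) {
    stop("targets must cover exactly the masked indices")
  }
  targets <- as.integer(targets)
  h <- unclass(ne)
  h2 <- h
  h2[idx, ] <- matrix(decoder$mask_vec, length(idx), ncol(h), byrow = TRUE)
  res <- gin_layer_forward(h2, gt$edge_index[1, ], gt$edge_index[2, ],
                           gt$edge_features[, 1], gt$edge_features[, 2],
                           decoder$layer, last = TRUE)
  dm <- res$out[idx, , drop = FALSE]
  pred <- sweep(dm %*% decoder$W, 2, decoder$b, "+")
  crit <- if (loss_type == "ce") softmax_ce(pred, targets) else
    scaled_cosine_loss(pred, targets)
  dpred <- if (loss_type == "ce") crit$dlogits else crit$dpred
  backward <- function() {
    dW <- crossprod(dm, dpred)
    db <- colSums(dpred)
    ddm <- tcrossprod(dpred, decoder$W)
    dout <- matrix(0, nrow(h), ncol(h))
    dout[idx, ] <- ddm
    bwd <- gin_layer_backward(dout, res$cache, decoder$layer)
    dh2 <- bwd$dh
    dmask_vec <- colSums(dh2[idx, , drop = FALSE])
    dne <- dh2
    dne[idx, ] <- 0  # re-masking cuts the gradient to masked embeddings
    list(dne = dne,
         ddecoder = list(mask_vec = dmask_vec, layer = bwd$grads,
                         W = dW, b = db))
  }
  structure(list(loss = crit$loss, masked_atom_accuracy = crit$accuracy,
                 n_masked = length(idx), backward = backward),
            class = "pretrain_batch_result")
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) return(lapply(p, zero_like))
    p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# One Adam update; params and grads must share structure.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
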