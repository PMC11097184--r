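# Graph isomorphism network (GIN) encoder.
#
# Message passing: h_v <- MLP( h_v + sum_{u in N(v)} (h_u + E(e_uv)) ),
# with typed-bond embeddings E added to neighbour messages, epsilon fixed
# at 0, each layer's MLP = linear -> ReLU -> linear, batch normalization
# after each layer, ReLU between layers but not after the last, and
# h_v^(0) = sum of node-feature embeddings. Implemented as plain matrix
# code with hand-derived reverse-mode gradients (validated against finite
# differences in the test suite); batch normalization always uses the
# statistics of the node batch at hand, which keeps evaluation
# deterministic and permutation-invariant.

#' Encoder configuration
#'
#' @param n_layers Number of GIN layers (default 5).
#' @param hidden_dim Embedding width (default 300).
#' @param dropout Dropout fraction applied after each layer's nonlinearity
#'   during training (default 0; fine-tuning conventionally uses 0.5).
#' @param readout Graph pooling: "mean" (default), "sum" or "max".
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 5L, hidden_dim = 300L, dropout = 0,
                           readout = c("mean", "sum", "max")) {
  readout <- match.arg(readout)
  stopifnot(n_layers >= 1L, hidden_dim >= 1L, dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 dropout = dropout, readout = readout),
            class = "encoder_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

gin_layer_params <- function(d) {
  vocab <- feature_vocab()
  list(ebt = glorot(vocab$bond_type, d),
       ebd = glorot(vocab$bond_dir, d),
       W1 = glorot(d, d), b1 = numeric(d),
       W2 = glorot(d, d), b2 = numeric(d),
       gamma = rep(1, d), beta = numeric(d))
}

#' Initialize encoder parameters
#'
#' Glorot-uniform linear maps and embedding tables; batch-norm scale 1,
#' shift 0. Draws from the current RNG stream (seed it, or pass `seed`).
#'
#' @param cfg An [encoder_config()].
#' @param seed Optional integer for a local RNG scope.
#' @return Nested list of parameter matrices/vectors.
#' @export
init_encoder_params <- function(cfg, seed = NULL) {
  init <- function() {
    vocab <- feature_vocab()
    d <- cfg$hidden_dim
    list(atom_emb = glorot(vocab$atom, d),
         chir_emb = glorot(vocab$chirality, d),
         layers = lapply(seq_len(cfg$n_layers), function(j) gin_layer_params(d)))
  }
  if (is.null(seed)) init() else withr::with_seed(seed, init())
}

# rowsum over groups 1..n with zero rows for absent groups.
rowsum_n <- function(x, group, n) {
  out <- matrix(0, n, ncol(x))
  if (length(group) == 0L) return(out)
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Combine several graph tensors into one batched graph
#'
#' Concatenates node rows and offsets edge indices; `graph_id` maps each
#' node back to its graph.
#'
#' @param gts List of `graph_tensors`.
#' @return A `graph_tensors` object with an extra `graph_id` integer
#'   vector and `n_graphs` count.
#' @export
batch_graphs <- function(gts) {
  sizes <- vapply(gts, function(g) g$n_nodes, 1L)
  offs <- cumsum(c(0L, utils::head(sizes, -1)))
  node_features <- do.call(rbind, lapply(gts, function(g) g$node_features))
  edge_index <- do.call(cbind, mapply(function(g, o) g$edge_index + o,
                                      gts, offs, SIMPLIFY = FALSE))
  edge_features <- do.call(rbind, lapply(gts, function(g) g$edge_features))
  structure(list(node_features = node_features,
                 edge_index = edge_index,
                 edge_features = edge_features,
                 n_nodes = sum(sizes),
                 n_graphs = length(gts),
                 graph_id = rep(seq_along(gts), sizes)),
            class = "graph_tensors")
}

BN_EPS <- 1e-5

# One GIN layer forward. Returns activations and everything backward needs.
gin_layer_forward <- function(h, src, dst, bt, bd, lp, last, dropout = 0,
                              training = FALSE) {
  n <- nrow(h)
  if (length(src) > 0L) {
    msg <- h[src, , drop = FALSE] + lp$ebt[bt, , drop = FALSE] +
      lp$ebd[bd, , drop = FALSE]
    agg <- rowsum_n(msg, dst, n)
  } else {
    agg <- matrix(0, n, ncol(h))
  }
  m <- h + agg
  a1 <- sweep(m %*% lp$W1, 2, lp$b1, "+")
  r <- pmax(a1, 0)
  a2 <- sweep(r %*% lp$W2, 2, lp$b2, "+")
  mu <- colMeans(a2)
  xc <- sweep(a2, 2, mu)
  va <- colMeans(xc^2)
  invstd <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(xc, 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, lp$gamma, "*"), 2, lp$beta, "+")
  out <- if (last) y else pmax(y, 0)
  dmask <- NULL
  if (training && dropout > 0) {
    dmask <- matrix((stats::runif(length(out)) >= dropout) / (1 - dropout),
                    nrow(out), ncol(out))
    out <- out * dmask
  }
  list(out = out,
       cache = list(src = src, dst = dst, bt = bt, bd = bd, m = m, a1 = a1,
                    r = r, xhat = xhat, invstd = invstd, y = y, last = last,
                    dmask = dmask, n = n))
}

# Reverse-mode gradients of one GIN layer: returns dh (w.r.t. the layer
# input) and the parameter gradients.
gin_layer_backward <- function(dout, cache, lp) {
  n <- cache$n
  if (!is.null(cache$dmask)) dout <- dout * cache$dmask
  dy <- if (cache$last) dout else dout * (cache$y > 0)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, lp$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  da2 <- sweep(
    dxhat - matrix(s1, n, length(s1), byrow = TRUE) / n -
      sweep(cache$xhat, 2, s2, "*") / n,
    2, cache$invstd, "*")
  dW2 <- crossprod(cache$r, da2)
  db2 <- colSums(da2)
  dr <- tcrossprod(da2, lp$W2)
  da1 <- dr * (cache$a1 > 0)
  dW1 <- crossprod(cache$m, da1)
  db1 <- colSums(da1)
  dm <- tcrossprod(da1, lp$W1)
  dh <- dm
  vocab <- feature_vocab()
  if (length(cache$src) > 0L) {
    dmsg <- dm[cache$dst, , drop = FALSE]
    dh <- dh + rowsum_n(dmsg, cache$src, n)
    debt <- rowsum_n(dmsg, cache$bt, vocab$bond_type)
    debd <- rowsum_n(dmsg, cache$bd, vocab$bond_dir)
  } else {
    debt <- matrix(0, vocab$bond_type, ncol(dh))
    debd <- matrix(0, vocab$bond_dir, ncol(dh))
  }
  list(dh = dh,
       grads = list(ebt = debt, ebd = debd, W1 = dW1, b1 = db1,
                    W2 = dW2, b2 = db2, gamma = dgamma, beta = dbeta))
}

# Full encoder forward with cache for backprop.
gin_forward <- function(gt, params, cfg, training = FALSE) {
  x <- gt$node_features
  h <- params$atom_emb[x[, 1], , drop = FALSE] +
    params$chir_emb[x[, 2], , drop = FALSE]
  src <- gt$edge_index[1, ]
  dst <- gt$edge_index[2, ]
  bt <- gt$edge_features[, 1]
  bd <- gt$edge_features[, 2]
  caches <- vector("list", cfg$n_layers)
  for (j in seq_len(cfg$n_layers)) {
    res <- gin_layer_forward(h, src, dst, bt, bd, params$layers[[j]],
                             last = (j == cfg$n_layers),
                             dropout = cfg$dropout, training = training)
    h <- res$out
    caches[[j]] <- res$cache
  }
  list(h = h, caches = caches, node_features = x)
}

# Full encoder backward: dH (n x d) -> gradients mirroring params.
gin_backward <- function(dH, fwd, params, cfg) {
  layer_grads <- vector("list", cfg$n_layers)
  for (j in rev(seq_len(cfg$n_layers))) {
    bwd <- gin_layer_backward(dH, fwd$caches[[j]], params$layers[[j]])
    dH <- bwd$dh
    layer_grads[[j]] <- bwd$grads
  }
  vocab <- feature_vocab()
  list(atom_emb = rowsum_n(dH, fwd$node_features[, 1], vocab$atom),
       chir_emb = rowsum_n(dH, fwd$node_features[, 2], vocab$chirality),
       layers = layer_grads)
}

#' Encode a (possibly corrupted) molecular graph
#'
#' Runs the configured number of GIN message-passing rounds and returns the
#' final-layer node embeddings. Deterministic given parameters and input.
#' Note that batch normalization uses the statistics of the node set passed
#' in, so embeddings of a molecule depend on which other molecules share
#' its batch; encode graphs in the same batch to compare them.
#'
#' @param gt A `graph_tensors` object (single graph or [batch_graphs()]
#'   output).
#' @param cfg An [encoder_config()].
#' @param params Parameters from [init_encoder_params()] or a checkpoint.
#' @return Object of class `node_embeddings`: matrix `n_nodes x hidden_dim`
#'   with attribute `graph_id` when the input was batched.
#' @export
encode <- function(gt, cfg, params) {
  stopifnot(inherits(gt, "graph_tensors"), inherits(cfg, "encoder_config"))
  if (ncol(params$atom_emb) != cfg$hidden_dim ||
      length(params$layers) != cfg$n_layers) {
    stop("parameter shapes do not match the encoder configuration")
  }
  h <- gin_forward(gt, params, cfg, training = FALSE)$h
  structure(h, class = c("node_embeddings", class(h)),
            graph_id = gt$graph_id %||% rep(1L, nrow(h)))
}

#' Pool node embeddings into graph embeddings
#'
#' Permutation-invariant readout over the final-layer node embeddings:
#' mean (default), sum, or coordinate-wise max per graph.
#'
#' @param ne A `node_embeddings` matrix (or any numeric matrix) with a
#'   `graph_id` attribute, or pass `graph_id` explicitly.
#' @param method "mean", "sum" or "max".
#' @param graph_id Optional integer vector mapping rows to graphs.
#' @return Matrix `n_graphs x hidden_dim` of graph embeddings.
#' @export
readout <- function(ne, method = c("mean", "sum", "max"), graph_id = NULL) {
  method <- match.arg(method)
  if (is.null(graph_id)) graph_id <- attr(ne, "graph_id")
  if (is.null(graph_id)) graph_id <- rep(1L, nrow(ne))
  if (nrow(ne) == 0L) stop("cannot pool an empty node set")
  ne <- unclass(ne)
  ng <- max(graph_id)
  if (method == "max") {
    out <- matrix(-Inf, ng, ncol(ne))
    for (g in seq_len(ng)) {
      out[g, ] <- apply(ne[graph_id == g, , drop = FALSE], 2, max)
    }
    return(out)
  }
  s <- rowsum_n(ne, graph_id, ng)
  if (method == "sum") s else s / as.numeric(table(factor(graph_id, seq_len(ng))))
}

# --- Checkpoints ------------------------------------------------------------

CHECKPOINT_VERSION <- "molmask-checkpoint-1"

params_to_plain <- function(p) {
  if (is.list(p)) return(lapply(p, params_to_plain))
  if (is.matrix(p)) return(list(.dim = dim(p), .data = as.numeric(p)))
  as.numeric(p)
}

plain_to_params <- function(p) {
  if (is.list(p) && !is.null(p$.dim)) {
    return(matrix(unlist(p$.data), p$.dim[[1]], p$.dim[[2]]))
  }
  if (is.list(p)) {
    scalar_leaf <- length(p) > 0L && is.null(names(p)) &&
      all(vapply(p, function(x) is.numeric(x) && length(x) == 1L, TRUE))
    if (scalar_leaf) return(as.numeric(unlist(p)))
    return(lapply(p, plain_to_params))
  }
  as.numeric(p)
}

#' Save encoder (and optional head) parameters to a checkpoint file
#'
#' Self-describing single-file JSON format: version tag, encoder config,
#' and full-precision parameters. [load_checkpoint()] validates the version
#' and restores the config.
#'
#' @param params Encoder parameter list.
#' @param cfg The [encoder_config()] the parameters belong to.
#' @param path Output file path.
#' @param extra Optional named list of additional serializable content
#'   (e.g. objective head parameters, training metadata).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, cfg, path, extra = NULL) {
  payload <- list(version = CHECKPOINT_VERSION,
                  config = unclass(cfg),
                  params = params_to_plain(params),
                  extra = if (!is.null(extra)) params_to_plain(extra))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file path.
#' @return List with `params`, `cfg` (an `encoder_config`) and `extra`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$version, CHECKPOINT_VERSION)) {
    stop("unrecognized checkpoint version: ", payload$version)
  }
  cfg <- do.call(encoder_config, payload$config)
  params <- plain_to_params(payload$params)
  d <- cfg$hidden_dim
  if (ncol(params$atom_emb) != d || length(params$layers) != cfg$n_layers) {
    stop("checkpoint parameters inconsistent with its config header")
  }
  extra <- if (!is.null(payload$extra)) plain_to_params(payload$extra)
  list(params = params, cfg = cfg, extra = extra)
}
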