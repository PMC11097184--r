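# Pretraining, scaffold splitting, fine-tuning, strategy comparison.
#
# Pretraining resamples masks independently every epoch for every molecule
# and logs a per-epoch accuracy curve. Fine-tuning trains a graph-level
# linear head (readout -> one logit per task) with missing-label masking,
# selects the epoch with the best validation ROC-AUC (ties to the earlier
# epoch) and reports the test ROC-AUC at that epoch; results are averaged
# over seeds. Everything is deterministic given the seeds.

#' Training configuration
#'
#' Paper-scale defaults are pretrain: 100 epochs, batch 256, dropout 0.0;
#' fine-tune: 100 epochs, batch 32, dropout 0.5; Adam with learning rate
#' 1e-3 for both. Desk-scale presets (see [desk_config()]) shrink the
#' encoder and epochs for laptop-sized experiments.
#'
#' @param stage "pretrain" or "finetune" (sets stage defaults).
#' @param epochs,batch_size,learning_rate,dropout Optimization settings.
#' @param mask_ratio Fraction of atoms masked per molecule (pretrain).
#' @param strategy Masking strategy: "random" or "wmm".
#' @param k WMM rarity-emphasis hyperparameter.
#' @param seed Integer seed governing initialization, shuffling, masking
#'   and dropout.
#' @param encoder An [encoder_config()].
#' @return Object of class `train_config`.
#' @export
train_config <- function(stage = c("pretrain", "finetune"),
                         epochs = 100L,
                         batch_size = NULL,
                         learning_rate = 1e-3,
                         dropout = NULL,
                         mask_ratio = 0.15,
                         strategy = c("random", "wmm"),
                         k = 0.9,
                         seed = 0L,
                         encoder = encoder_config()) {
  stage <- match.arg(stage)
  strategy <- match.arg(strategy)
  if (is.null(batch_size)) batch_size <- if (stage == "pretrain") 256L else 32L
  if (is.null(dropout)) dropout <- if (stage == "pretrain") 0 else 0.5
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            mask_ratio > 0, mask_ratio <= 1)
  encoder$dropout <- dropout
  structure(list(stage = stage, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 mask_ratio = mask_ratio, strategy = strategy, k = k,
                 seed = as.integer(seed), encoder = encoder),
            class = "train_config")
}

#' Desk-scale training configuration preset
#'
#' A small encoder (3 layers, width 64) and short schedules so the whole
#' pretrain + fine-tune pipeline runs in minutes on one CPU. All fields
#' remain overridable via `...` (passed to [train_config()]).
#'
#' @param stage "pretrain" or "finetune".
#' @param ... Overrides forwarded to [train_config()].
#' @return A `train_config`.
#' @export
desk_config <- function(stage = c("pretrain", "finetune"), ...) {
  stage <- match.arg(stage)
  args <- list(...)
  if (is.null(args$encoder)) {
    args$encoder <- encoder_config(n_layers = 3L, hidden_dim = 64L)
  }
  if (is.null(args$epochs)) args$epochs <- if (stage == "pretrain") 30L else 20L
  if (is.null(args$batch_size)) args$batch_size <- 64L
  do.call(train_config, c(list(stage = stage), args))
}

# Sample a mask plan for one molecule under the configured strategy,
# consuming the current RNG stream.
sample_plan <- function(mol, cfg) {
  if (cfg$strategy == "wmm") {
    sample_mask_wmm(mol, wmm_config(k = cfg$k, mask_ratio = cfg$mask_ratio))
  } else {
    sample_mask_random(mol, cfg$mask_ratio)
  }
}

#' Pretrain an encoder with a masked-atom objective
#'
#' Runs the configured objective over the corpus with per-epoch resampled
#' masks, optimized by Adam, and logs the per-epoch mean masked-atom
#' prediction accuracy and loss (the accuracy curve). Fully reproducible
#' given `cfg$seed`.
#'
#' @param corpus List of `mol_graph`s.
#' @param objective "attrmask" or "graphmae".
#' @param cfg A [train_config()] (stage "pretrain").
#' @param loss_type GraphMAE reconstruction loss, "ce" or "sce".
#' @return List with `params` (encoder parameters), `head` (objective
#'   parameters), `cfg` (the encoder config) and `curve` (data frame:
#'   `epoch`, `accuracy`, `loss`). Save with [save_checkpoint()].
#' @export
pretrain <- function(corpus, objective = c("attrmask", "graphmae"), cfg,
                     loss_type = "ce") {
  objective <- match.arg(objective)
  stopifnot(inherits(cfg, "train_config"), length(corpus) >= 1L)
  ecfg <- cfg$encoder
  gts <- lapply(corpus, featurize)
  withr::with_seed(cfg$seed, {
    params <- init_encoder_params(ecfg)
    head <- if (objective == "attrmask") init_attrmask_head(ecfg$hidden_dim)
            else init_graphmae_decoder(ecfg$hidden_dim)
    opt <- adam_init(list(enc = params, head = head))
    curve <- data.frame(epoch = integer(0), accuracy = numeric(0),
                        loss = numeric(0))
    n <- length(corpus)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot_correct <- 0; tot_loss <- 0; tot_masked <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ids <- ord[start:min(n, start + cfg$batch_size - 1L)]
        plans <- lapply(ids, function(i) sample_plan(corpus[[i]], cfg))
        masked <- mapply(function(i, p) apply_mask(gts[[i]], p),
                         ids, plans, SIMPLIFY = FALSE)
        bg <- batch_graphs(lapply(masked, `[[`, "corrupted"))
        offs <- cumsum(c(0L, utils::head(vapply(ids, function(i) gts[[i]]$n_nodes, 1L), -1)))
        idx <- unlist(mapply(function(p, o) p$masked_indices + o,
                             plans, offs, SIMPLIFY = FALSE))
        targets <- as.integer(unlist(lapply(masked, `[[`, "targets")))
        plan <- new_mask_plan(idx, NULL, cfg$strategy)
        fwd <- gin_forward(bg, params, ecfg, training = TRUE)
        obj <- if (objective == "attrmask") {
          attrmask_objective(fwd$h, plan, targets, head)
        } else {
          graphmae_objective(fwd$h, bg, plan, targets, head,
                             loss_type = loss_type)
        }
        bk <- obj$backward()
        enc_grads <- gin_backward(bk$dne, fwd, params, ecfg)
        head_grads <- if (objective == "attrmask") bk$dhead else bk$ddecoder
        st <- adam_step(list(enc = params, head = head),
                        list(enc = enc_grads, head = head_grads),
                        opt, lr = cfg$learning_rate)
        params <- st$params$enc
        head <- st$params$head
        opt <- st$state
        m <- obj$n_masked
        tot_correct <- tot_correct + obj$masked_atom_accuracy * m
        tot_loss <- tot_loss + obj$loss * m
        tot_masked <- tot_masked + m
      }
      curve <- rbind(curve, data.frame(epoch = epoch,
                                       accuracy = tot_correct / tot_masked,
                                       loss = tot_loss / tot_masked))
    }
    list(params = params, head = head, cfg = ecfg, curve = curve)
  })
}

# --- Scaffold split ---------------------------------------------------------

# Bemis-Murcko scaffold: iteratively prune degree-1 atoms; what remains is
# the ring systems plus linkers. Returns the atom indices of the scaffold
# (possibly empty for acyclic molecules).
murcko_scaffold_atoms <- function(mol) {
  n <- n_atoms(mol)
  alive <- rep(TRUE, n)
  deg <- integer(n)
  b <- mol$bonds
  for (e in seq_len(nrow(b))) {
    deg[b$u[e]] <- deg[b$u[e]] + 1L
    deg[b$v[e]] <- deg[b$v[e]] + 1L
  }
  repeat {
    leaf <- which(alive & deg <= 1L)
    if (length(leaf) == 0L) break
    alive[leaf] <- FALSE
    for (e in seq_len(nrow(b))) {
      u <- b$u[e]; v <- b$v[e]
      if (alive[u] && !alive[v] && v %in% leaf) deg[u] <- deg[u] - 1L
      if (alive[v] && !alive[u] && u %in% leaf) deg[v] <- deg[v] - 1L
    }
    deg[leaf] <- 0L
  }
  which(alive)
}

#' Canonical Bemis-Murcko scaffold key of a molecule
#'
#' Groups molecules by scaffold: the molecular graph with all acyclic
#' side chains pruned away. The key is a canonical serialization (igraph
#' BLISS canonical permutation with element and bond-type colors), so two
#' molecules share a key iff their scaffolds are isomorphic as typed
#' graphs. Acyclic molecules all map to the empty scaffold key `""`.
#'
#' @param mol A [mol_graph()].
#' @return Character scaffold key.
#' @export
murcko_scaffold_key <- function(mol) {
  keep <- murcko_scaffold_atoms(mol)
  if (length(keep) == 0L) return("")
  remap <- match(seq_len(n_atoms(mol)), keep)
  b <- mol$bonds
  inb <- !is.na(remap[b$u]) & !is.na(remap[b$v])
  b <- b[inb, , drop = FALSE]
  ns <- length(keep)
  nb <- nrow(b)
  # vertices: scaffold atoms colored by element, one extra vertex per bond
  # colored by 118 + bond type, connected to the bond's endpoints
  edges <- integer(0)
  for (e in seq_len(nb)) {
    bv <- ns + e
    edges <- c(edges, remap[b$u[e]], bv, remap[b$v[e]], bv)
  }
  g <- igraph::make_graph(edges, n = ns + nb, directed = FALSE)
  colors <- c(mol$atoms$z[keep], 118L + match(b$type, BOND_TYPES))
  cp <- igraph::canonical_permutation(g, colors = colors)
  gc <- igraph::permute(g, cp$labeling)
  colc <- colors[order(cp$labeling)]
  el <- igraph::as_edgelist(gc)
  el <- el[order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), , drop = FALSE]
  paste(paste(colc, collapse = ","),
        paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
              sep = "-", collapse = ","),
        sep = "|")
}

#' Deterministic scaffold split
#'
#' Groups molecules by Bemis-Murcko scaffold, orders groups by size
#' (largest first, ties by first occurrence), then fills train, validation
#' and test greedily to the target fractions. A group that alone exceeds
#' the current partition's remaining capacity is placed whole into the
#' currently least-filled later partition (ties to the earlier one); no
#' scaffold is ever split across partitions.
#'
#' @param mols List of `mol_graph`s (or precomputed scaffold keys as a
#'   character vector).
#' @param fractions Target train/valid/test fractions (default 80/10/10).
#' @return Object of class `split_result`: list with `train`, `valid`,
#'   `test` (integer index vectors), and `method = "scaffold"`.
#' @export
scaffold_split <- function(mols, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  keys <- if (is.character(mols)) mols else
    vapply(mols, murcko_scaffold_key, "")
  n <- length(keys)
  groups <- split(seq_len(n), factor(keys, levels = unique(keys)))
  if (length(groups) < 3L) {
    stop("fewer scaffold groups (", length(groups),
         ") than partitions: cannot scaffold-split")
  }
  sizes <- lengths(groups)
  ord <- order(-sizes, vapply(groups, min, 1L))
  groups <- groups[ord]
  targets <- fractions * n
  filled <- c(train = 0L, valid = 0L, test = 0L)
  assign_to <- list(train = integer(0), valid = integer(0), test = integer(0))
  current <- 1L
  for (g in groups) {
    while (current < 3L && filled[current] >= targets[current] - 1e-9) {
      current <- current + 1L
    }
    size <- length(g)
    dest <- current
    if (current < 3L && filled[current] + size > targets[current] + 1e-9) {
      later <- seq(current + 1L, 3L)
      dest <- later[which.min(filled[later])]
    }
    assign_to[[dest]] <- c(assign_to[[dest]], g)
    filled[dest] <- filled[dest] + size
  }
  structure(list(train = sort(assign_to$train),
                 valid = sort(assign_to$valid),
                 test = sort(assign_to$test),
                 method = "scaffold"),
            class = "split_result")
}

# --- ROC-AUC ----------------------------------------------------------------

# Mean ROC-AUC over tasks with both classes present; single-class tasks are
# skipped with a warning (returns NA if no task is scorable).
mean_task_auc <- function(labels, scores, warn = TRUE) {
  aucs <- vapply(seq_len(ncol(labels)), function(t) {
    y <- labels[, t]
    s <- scores[, t]
    ok <- !is.na(y)
    if (length(unique(y[ok])) < 2L) {
      if (warn) warning("task ", t, " has a single class; excluded from mean ROC-AUC")
      return(NA_real_)
    }
    as.numeric(pROC::auc(y[ok], s[ok], direction = "<", quiet = TRUE,
                         levels = c(0, 1)))
  }, numeric(1))
  if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE)
}

# Masked binary cross-entropy on logits; returns loss and dlogits.
masked_bce <- function(logits, labels) {
  obs <- !is.na(labels)
  m <- sum(obs)
  p <- 1 / (1 + exp(-logits))
  eps <- 1e-12
  y <- labels
  loss_mat <- -(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  loss <- sum(loss_mat[obs]) / m
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[obs] <- (p[obs] - y[obs]) / m
  list(loss = loss, dlogits = dlogits)
}

# Forward pass for property prediction: graph embedding -> task logits.
predict_scores <- function(mols_gts, params, ecfg, head) {
  bg <- batch_graphs(mols_gts)
  h <- gin_forward(bg, params, ecfg, training = FALSE)$h
  hg <- readout(h, ecfg$readout, graph_id = bg$graph_id)
  sweep(hg %*% head$W, 2, head$b, "+")
}

#' Fine-tune a pretrained encoder for multi-task property prediction
#'
#' Attaches a graph-level linear head (readout, then one logit per task),
#' trains encoder + head with masked binary cross-entropy under a scaffold
#' split, and evaluates mean ROC-AUC over tasks each epoch. Per seed, the
#' reported test ROC-AUC is the one at the epoch with the best validation
#' ROC-AUC (ties to the earlier epoch). The aggregate is mean and standard
#' deviation over seeds.
#'
#' @param checkpoint Pretraining result from [pretrain()] or
#'   [load_checkpoint()] (list with `params` and `cfg`).
#' @param mols List of `mol_graph`s.
#' @param labels Matrix `n x n_tasks` of 0/1/NA labels.
#' @param cfg A [train_config()] (stage "finetune"); its encoder config is
#'   overridden by the checkpoint's.
#' @param seeds Integer vector of fine-tuning seeds.
#' @param split Optional precomputed [scaffold_split()]; computed from
#'   `mols` when NULL.
#' @return List with `per_seed` (data frame: seed, best_epoch, valid_auc,
#'   test_auc), `mean`, `sd`, `split`, and `history` (per-seed data frames
#'   of per-epoch metrics).
#' @export
finetune <- function(checkpoint, mols, labels, cfg, seeds = 0:9,
                     split = NULL) {
  stopifnot(inherits(cfg, "train_config"), is.matrix(labels),
            length(mols) == nrow(labels))
  ecfg <- checkpoint$cfg
  ecfg$dropout <- cfg$dropout
  if (is.null(split)) split <- scaffold_split(mols)
  gts <- lapply(mols, featurize)
  n_tasks <- ncol(labels)
  run_seed <- function(seed) {
    withr::with_seed(as.integer(seed), {
      params <- checkpoint$params
      head <- list(W = glorot(ecfg$hidden_dim, n_tasks), b = numeric(n_tasks))
      opt <- adam_init(list(enc = params, head = head))
      tr <- split$train
      hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                         valid_auc = numeric(0), test_auc = numeric(0))
      for (epoch in seq_len(cfg$epochs)) {
        ord <- sample(tr)
        ep_loss <- 0; ep_n <- 0L
        for (start in seq(1L, length(ord), by = cfg$batch_size)) {
          ids <- ord[start:min(length(ord), start + cfg$batch_size - 1L)]
          bg <- batch_graphs(gts[ids])
          fwd <- gin_forward(bg, params, ecfg, training = TRUE)
          hg <- readout(fwd$h, ecfg$readout, graph_id = bg$graph_id)
          logits <- sweep(hg %*% head$W, 2, head$b, "+")
          bce <- masked_bce(logits, labels[ids, , drop = FALSE])
          dW <- crossprod(hg, bce$dlogits)
          db <- colSums(bce$dlogits)
          dhg <- tcrossprod(bce$dlogits, head$W)
          # mean readout: each node receives its graph gradient / graph size
          sizes <- as.numeric(table(factor(bg$graph_id, seq_along(ids))))
          dH <- dhg[bg$graph_id, , drop = FALSE]
          if (ecfg$readout == "mean") dH <- dH / sizes[bg$graph_id]
          enc_grads <- gin_backward(dH, fwd, params, ecfg)
          st <- adam_step(list(enc = params, head = head),
                          list(enc = enc_grads, head = list(W = dW, b = db)),
                          opt, lr = cfg$learning_rate)
          params <- st$params$enc; head <- st$params$head; opt <- st$state
          ep_loss <- ep_loss + bce$loss * length(ids); ep_n <- ep_n + length(ids)
        }
        sv <- predict_scores(gts[split$valid], params, ecfg, head)
        stst <- predict_scores(gts[split$test], params, ecfg, head)
        va <- mean_task_auc(labels[split$valid, , drop = FALSE], sv, warn = FALSE)
        ta <- mean_task_auc(labels[split$test, , drop = FALSE], stst,
                            warn = (epoch == 1L))
        hist <- rbind(hist, data.frame(epoch = epoch,
                                       train_loss = ep_loss / ep_n,
                                       valid_auc = va, test_auc = ta))
      }
      best <- which.max(hist$valid_auc)  # which.max ties to the earlier epoch
      if (length(best) == 0L) best <- nrow(hist)  # no scorable valid task
      list(hist = hist,
           row = data.frame(seed = seed, best_epoch = hist$epoch[best],
                            valid_auc = hist$valid_auc[best],
                            test_auc = hist$test_auc[best]))
    })
  }
  runs <- lapply(seeds, run_seed)
  per_seed <- do.call(rbind, lapply(runs, `[[`, "row"))
  list(per_seed = per_seed,
       mean = mean(per_seed$test_auc),
       sd = stats::sd(per_seed$test_auc),
       split = split,
       history = lapply(runs, `[[`, "hist"))
}

#' Compare pretraining arms end to end
#'
#' Pretrains one encoder per arm on the corpus and fine-tunes each on the
#' labeled dataset(s), emitting one table row per arm with per-dataset
#' mean +/- sd test ROC-AUC and an overall average column. Deterministic
#' given the configured seeds.
#'
#' @param corpus List of `mol_graph`s for pretraining.
#' @param datasets Named list; each element is `list(mols =, labels =)`.
#' @param arms Named list; each element is a list with `objective`
#'   ("attrmask"/"graphmae"), `strategy` ("random"/"wmm"), and optional
#'   `k`, `mask_ratio`.
#' @param pretrain_cfg,finetune_cfg Base [train_config()]s; each arm's
#'   strategy fields override the pretrain config.
#' @param seeds Fine-tuning seeds.
#' @return Data frame: one row per arm with columns `arm`, `objective`,
#'   `strategy`, `k`, then `<dataset>_mean`, `<dataset>_sd` per dataset and
#'   `avg`.
#' @export
compare_strategies <- function(corpus, datasets, arms,
                               pretrain_cfg = desk_config("pretrain"),
                               finetune_cfg = desk_config("finetune"),
                               seeds = 0:2) {
  stopifnot(length(arms) >= 1L, !is.null(names(arms)),
            length(datasets) >= 1L, !is.null(names(datasets)))
  splits <- lapply(datasets, function(d) scaffold_split(d$mols))
  rows <- lapply(names(arms), function(nm) {
    arm <- arms[[nm]]
    pcfg <- pretrain_cfg
    pcfg$strategy <- arm$strategy %||% "random"
    if (!is.null(arm$k)) pcfg$k <- arm$k
    if (!is.null(arm$mask_ratio)) pcfg$mask_ratio <- arm$mask_ratio
    ckpt <- pretrain(corpus, arm$objective %||% "attrmask", pcfg)
    row <- data.frame(arm = nm, objective = arm$objective %||% "attrmask",
                      strategy = pcfg$strategy,
                      k = if (pcfg$strategy == "wmm") pcfg$k else NA_real_,
                      stringsAsFactors = FALSE)
    means <- numeric(0)
    for (ds in names(datasets)) {
      ft <- finetune(ckpt, datasets[[ds]]$mols, datasets[[ds]]$labels,
                     finetune_cfg, seeds = seeds, split = splits[[ds]])
      row[[paste0(ds, "_mean")]] <- ft$mean
      row[[paste0(ds, "_sd")]] <- ft$sd
      means <- c(means, ft$mean)
    }
    row$avg <- mean(means)
    row
  })
  do.call(rbind, rows)
}

#' Write a comparison table as TSV
#'
#' Fixed-format serialization (numbers at 6 decimal places) so identical
#' runs produce byte-identical files.
#'
#' @param table Data frame from [compare_strategies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(table, path) {
  fmt <- table
  num <- vapply(fmt, is.numeric, TRUE)
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.6f", x))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
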