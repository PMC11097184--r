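# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_corpus <- function(n = 60L, seed = 101L) {
  cached(sprintf("corpus_%d_%d", n, seed),
         function() generate_corpus(corpus_spec(n, seed = seed)))
}

toy_mols <- function() {
  cached("toy_mols", function() {
    lapply(c("CCO", "c1ccccc1", "C", "FC(F)(F)F", "CCC(C)Cl",
             "CC(=O)Nc1ccc(Cl)c(Cl)c1Cl", "CC(N)Cc1ccccc1F", "OCC(O)C(O)CO"),
           parse_smiles)
  })
}

tiny_encoder <- function(d = 8L, layers = 2L) encoder_config(layers, d)

# A small batched masked graph plus everything the objectives need.
masked_batch <- function(mols, d = 8L, layers = 2L, seed = 7L,
                         mask_ratio = 0.3, k = 0.9) {
  gts <- lapply(mols, featurize)
  plans <- lapply(seq_along(mols), function(i) {
    sample_mask_wmm(mols[[i]], wmm_config(k, mask_ratio), seed = seed + i)
  })
  masked <- mapply(function(g, p) apply_mask(g, p), gts, plans,
                   SIMPLIFY = FALSE)
  bg <- batch_graphs(lapply(masked, `[[`, "corrupted"))
  sizes <- vapply(gts, function(g) g$n_nodes, 1L)
  offs <- cumsum(c(0L, utils::head(sizes, -1)))
  idx <- unlist(mapply(function(p, o) p$masked_indices + o, plans, offs,
                       SIMPLIFY = FALSE))
  targets <- as.integer(unlist(lapply(masked, `[[`, "targets")))
  plan <- structure(list(masked_indices = as.integer(idx), M = length(idx),
                         per_atom_weight = NULL, strategy = "wmm"),
                    class = "mask_plan")
  list(bg = bg, plan = plan, targets = targets,
       cfg = tiny_encoder(d, layers))
}

# Central-difference gradient check of `loss_fn` w.r.t. sampled coordinates
# of one parameter leaf accessed by get/set closures.
fd_check <- function(loss_fn, get, set, analytic, n_coords = 4L,
                     eps = 1e-5) {
  errs <- vapply(seq_len(n_coords), function(i) {
    co <- sample.int(length(analytic), 1L)
    p0 <- get()
    p <- p0; p[co] <- p[co] + eps; set(p); lp <- loss_fn()
    p <- p0; p[co] <- p[co] - eps; set(p); lm <- loss_fn()
    set(p0)
    fd <- (lp - lm) / (2 * eps)
    abs(fd - analytic[co]) / max(1e-8, abs(fd) + abs(analytic[co]))
  }, numeric(1))
  max(errs)
}
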