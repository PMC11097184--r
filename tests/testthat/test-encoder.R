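test_that("encode is permutation-equivariant and readout invariant", {
  set.seed(21)
  cfg <- tiny_encoder(16L, 3L)
  params <- init_encoder_params(cfg, seed = 2)
  mols <- toy_corpus(20L, seed = 55L)
  for (mol in mols[1:8]) {
    n <- n_atoms(mol)
    if (n < 2L) next
    gt <- featurize(mol)
    h <- encode(gt, cfg, params)
    for (rep in 1:3) {
      perm <- sample(n)
      hp <- encode(featurize(permute_mol(mol, perm)), cfg, params)
      expect_equal(unclass(hp)[perm, ], unclass(h), tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(readout(hp), readout(h), tolerance = 1e-8)
    }
  }
})

test_that("isomorphic featurizations give identical embedding multisets", {
  cfg <- tiny_encoder(8L, 2L)
  params <- init_encoder_params(cfg, seed = 5)
  benzene <- parse_smiles("c1ccccc1")
  rotated <- permute_mol(benzene, c(2:6, 1))  # a ring rotation
  h1 <- unclass(encode(featurize(benzene), cfg, params))
  h2 <- unclass(encode(featurize(rotated), cfg, params))
  o1 <- h1[do.call(order, as.data.frame(h1)), ]
  o2 <- h2[do.call(order, as.data.frame(h2)), ]
  expect_equal(o1, o2, tolerance = 1e-8)
})

test_that("a single node with no edges encodes from its own features", {
  cfg <- tiny_encoder(8L, 2L)
  params <- init_encoder_params(cfg, seed = 5)
  h <- encode(featurize(parse_smiles("C")), cfg, params)
  expect_equal(dim(unclass(h)), c(1L, 8L))
  expect_true(all(is.finite(h)))
  expect_equal(unname(readout(h)[1, ]), unname(unclass(h)[1, ]))
})

test_that("embeddings stay finite on random parameters across a corpus", {
  cfg <- tiny_encoder(16L, 3L)
  params <- init_encoder_params(cfg, seed = 77)
  bg <- batch_graphs(lapply(toy_corpus(30L, seed = 9L), featurize))
  h <- encode(bg, cfg, params)
  expect_true(all(is.finite(h)))
  expect_equal(nrow(unclass(h)), bg$n_nodes)
})

test_that("readout pools per graph under mean, sum and max", {
  m <- matrix(c(1, 2, 3, 5, 7, 11), ncol = 2)
  gid <- c(1L, 1L, 2L)
  expect_equal(readout(m, "mean", gid), matrix(c(1.5, 3, 6, 11), 2))
  expect_equal(readout(m, "sum", gid), matrix(c(3, 3, 12, 11), 2))
  expect_equal(readout(m, "max", gid), matrix(c(2, 3, 7, 11), 2))
  # constant node vectors pool to the constant
  cm <- matrix(4, 5, 3)
  expect_equal(readout(cm, "mean", rep(1L, 5)), matrix(4, 1, 3))
  expect_error(readout(matrix(numeric(0), 0, 3), "mean", integer(0)),
               "empty")
})

test_that("duplicated graphs pool to identical embeddings per copy", {
  cfg <- tiny_encoder(8L, 2L)
  params <- init_encoder_params(cfg, seed = 1)
  gt <- featurize(parse_smiles("CCOCC"))
  bg <- batch_graphs(list(gt, gt))
  h <- encode(bg, cfg, params)
  hg <- readout(h, "mean", graph_id = bg$graph_id)
  expect_equal(hg[1, ], hg[2, ], tolerance = 1e-10)
})

test_that("batch_graphs offsets edges and tracks graph membership", {
  gts <- lapply(list("CCO", "C", "c1ccccc1"), function(s) featurize(parse_smiles(s)))
  bg <- batch_graphs(gts)
  expect_equal(bg$n_nodes, 10L)
  expect_equal(bg$graph_id, rep(1:3, c(3L, 1L, 6L)))
  expect_equal(ncol(bg$edge_index), 4L + 0L + 12L)
  expect_true(all(bg$edge_index[, 1:4] <= 3))
  expect_true(all(bg$edge_index[, 5:16] >= 5))
})

test_that("encoder and head gradients match finite differences", {
  set.seed(31)
  mb <- masked_batch(toy_mols()[c(1, 5, 6)], d = 8L, layers = 2L)
  params <- init_encoder_params(mb$cfg, seed = 3)
  head <- withr::with_seed(4, init_attrmask_head(8L))
  loss_fn <- function() {
    fwd <- molmask:::gin_forward(mb$bg, params, mb$cfg)
    attrmask_objective(fwd$h, mb$plan, mb$targets, head)$loss
  }
  fwd <- molmask:::gin_forward(mb$bg, params, mb$cfg)
  obj <- attrmask_objective(fwd$h, mb$plan, mb$targets, head)
  bk <- obj$backward()
  g <- molmask:::gin_backward(bk$dne, fwd, params, mb$cfg)

  expect_lt(fd_check(loss_fn, function() params$layers[[1]]$W1,
                     function(p) params$layers[[1]]$W1 <<- p,
                     g$layers[[1]]$W1), 1e-5)
  expect_lt(fd_check(loss_fn, function() params$layers[[2]]$W2,
                     function(p) params$layers[[2]]$W2 <<- p,
                     g$layers[[2]]$W2), 1e-5)
  expect_lt(fd_check(loss_fn, function() params$layers[[1]]$gamma,
                     function(p) params$layers[[1]]$gamma <<- p,
                     g$layers[[1]]$gamma), 1e-5)
  expect_lt(fd_check(loss_fn, function() params$layers[[2]]$ebt,
                     function(p) params$layers[[2]]$ebt <<- p,
                     g$layers[[2]]$ebt), 1e-4)
  expect_lt(fd_check(loss_fn, function() head$W,
                     function(p) head$W <<- p, bk$dhead$W), 1e-5)
})

test_that("checkpoints round-trip parameters, config and version", {
  cfg <- tiny_encoder(8L, 2L)
  params <- init_encoder_params(cfg, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(params, cfg, path, extra = list(note = c(1, 2, 3)))
  ck <- load_checkpoint(path)
  expect_equal(ck$params, params, tolerance = 1e-14)
  expect_equal(ck$cfg$hidden_dim, 8L)
  expect_equal(ck$cfg$n_layers, 2L)
  expect_equal(ck$extra$note, c(1, 2, 3))
  # tampered version tag is rejected
  txt <- readLines(path)
  writeLines(sub("molmask-checkpoint-1", "bogus-0", txt), path)
  expect_error(load_checkpoint(path), "version")
})
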