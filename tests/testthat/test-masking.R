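test_that("count_atom_types tallies elements within one molecule", {
  tc <- count_atom_types(parse_smiles("CCO"))
  expect_equal(tc$counts, c(C = 2L, O = 1L))
  expect_equal(tc$total, 3L)
  expect_equal(count_atom_types(parse_smiles("c1ccccc1"))$counts, c(C = 6L))
  expect_equal(count_atom_types(parse_smiles("FC(F)(F)F"))$counts,
               c(F = 4L, C = 1L))
})

test_that("atom_weight matches ln(k(n+1))/n and rejects the bad domain", {
  expect_equal(atom_weight(1, 1.0), 0.693147180559945, tolerance = 1e-12)
  expect_equal(atom_weight(10, 0.9), 0.229253475714054, tolerance = 1e-12)
  expect_gt(atom_weight(1, 0.8), atom_weight(2, 0.8))
  expect_equal(atom_weight(1, 0.8), 0.470003629245736, tolerance = 1e-12)
  expect_equal(atom_weight(2, 0.8), 0.437734368676950, tolerance = 1e-12)
  expect_error(atom_weight(1, 0.4), "non-positive")
})

test_that("expected masked counts normalize to M and follow the counts", {
  m <- expected_masked_counts(c(C = 7, O = 2, N = 1), M = 2, k = 0.9)
  expect_equal(unname(m), c(1.110556787780805, 0.558772656213956,
                            0.330670556005239), tolerance = 1e-12)
  expect_equal(sum(m), 2, tolerance = 1e-12)
  # single type takes the whole budget
  expect_equal(unname(expected_masked_counts(c(C = 6), 4, 1.1)), 4)
  # symmetry of equal counts
  m2 <- expected_masked_counts(c(C = 3, O = 3), 2, 1.0)
  expect_equal(unname(m2), c(1, 1))
  expect_error(expected_masked_counts(c(C = 2), 3, 1.0), "exceeds")
})

test_that("weights decrease in n, expectations increase, k-gap narrows", {
  n <- 1:50
  for (k in c(0.8, 0.9, 1.0, 1.1, 1.2)) {
    w <- atom_weight(n, k)
    expect_true(all(diff(w) < 0))
  }
  # within one molecule, a more frequent type expects more masked atoms
  set.seed(3)
  for (rep in 1:20) {
    counts <- sort(sample(1:30, 4))
    names(counts) <- c("S", "N", "O", "C")
    counts <- counts[!duplicated(counts)]
    m <- expected_masked_counts(counts, M = 2, k = 0.9)
    expect_true(all(diff(m[order(counts)]) > 0))
  }
  gap <- abs(atom_weight(n, 1.2) - atom_weight(n, 0.8))
  expect_true(all(diff(gap) < 0))
})

test_that("the mask budget rounds half-up with a floor of one atom", {
  mol20 <- generate_corpus(corpus_spec(1, atom_budget = c(20, 20), seed = 1))[[1]]
  plan <- sample_mask_random(mol20, 0.15, seed = 1)
  expect_equal(plan$M, 3L)
  single <- parse_smiles("C")
  expect_equal(sample_mask_random(single, 0.15, seed = 1)$masked_indices, 1L)
  expect_equal(sample_mask_wmm(single, wmm_config(), seed = 1)$masked_indices, 1L)
})

test_that("wmm_config validates k and mask_ratio", {
  expect_error(wmm_config(k = 1.5), "0.8, 1.2")
  expect_s3_class(wmm_config(k = 1.5, unsafe = TRUE), "wmm_config")
  expect_error(wmm_config(k = 0.4, unsafe = TRUE), "non-positive|0.5")
  expect_error(wmm_config(mask_ratio = 0), "mask_ratio")
})

test_that("samplers are deterministic given a seed and produce valid plans", {
  mol <- parse_smiles("CC(=O)Nc1ccc(Cl)c(Cl)c1Cl")
  cfg <- wmm_config(0.9, 0.25)
  p1 <- sample_mask_wmm(mol, cfg, seed = 11)
  p2 <- sample_mask_wmm(mol, cfg, seed = 11)
  expect_identical(p1$masked_indices, p2$masked_indices)
  expect_equal(p1$M, length(p1$masked_indices))
  expect_true(all(p1$masked_indices >= 1 & p1$masked_indices <= n_atoms(mol)))
  expect_true(all(p1$per_atom_weight > 0))
  r1 <- sample_mask_random(mol, 0.25, seed = 11)
  r2 <- sample_mask_random(mol, 0.25, seed = 11)
  expect_identical(r1$masked_indices, r2$masked_indices)
})

test_that("brute-force inclusion probabilities satisfy closed-form cases", {
  expect_equal(inclusion_probabilities_bruteforce(rep(1, 4), 2),
               rep(0.5, 4))
  expect_equal(inclusion_probabilities_bruteforce(c(0.3, 2, 5), 3),
               rep(1, 3))
  expect_equal(inclusion_probabilities_bruteforce(c(1, 1, 2), 1),
               c(0.25, 0.25, 0.5))
  expect_equal(sum(inclusion_probabilities_bruteforce(c(0.2, 1, 3, 0.7), 2)),
               2, tolerance = 1e-12)
  expect_error(inclusion_probabilities_bruteforce(rep(1, 9), 2), "N > 8")
})

test_that("the weighted sampler tracks its enumeration oracle", {
  mol <- parse_smiles("CCC(C)Cl")  # counts C:4, Cl:1
  w <- atom_weight(c(4, 4, 4, 4, 1), 0.9)
  exact <- inclusion_probabilities_bruteforce(w, 2)
  draws <- 30000
  sel <- withr::with_seed(5, molmask:::wmm_draw_many(w, 2L, draws))
  emp <- tabulate(c(sel), 5) / draws
  sigma <- sqrt(exact * (1 - exact) / draws)
  expect_true(all(abs(emp - exact) <= 3 * sigma))
})

test_that("apply_mask corrupts only the planned nodes and round-trips", {
  mol <- parse_smiles("CC(=O)Nc1ccc(Cl)c(Cl)c1Cl")
  gt <- featurize(mol)
  plan <- sample_mask_wmm(mol, wmm_config(0.9, 0.25), seed = 3)
  res <- apply_mask(gt, plan)
  vocab <- feature_vocab()
  idx <- plan$masked_indices
  expect_true(all(res$corrupted$node_features[idx, 1] == vocab$mask_token))
  expect_true(all(res$corrupted$node_features[idx, 2] == 1L))
  expect_equal(res$corrupted$node_features[-idx, ], gt$node_features[-idx, ])
  expect_identical(res$corrupted$edge_index, gt$edge_index)
  expect_identical(res$corrupted$edge_features, gt$edge_features)
  # input untouched, restoration recovers the original
  expect_false(any(gt$node_features[, 1] == vocab$mask_token))
  restored <- res$corrupted
  restored$node_features[idx, 1] <- res$targets
  restored$node_features[idx, 2] <- gt$node_features[idx, 2]
  expect_equal(restored$node_features, gt$node_features)
  # full masking
  full <- apply_mask(gt, sample_mask_wmm(mol, wmm_config(0.9, 1), seed = 1))
  expect_true(all(full$corrupted$node_features[, 1] == vocab$mask_token))
  bad <- plan
  bad$masked_indices <- c(1L, 99L)
  expect_error(apply_mask(gt, bad), "out of range")
})

test_that("mask distribution report normalizes and degenerates correctly", {
  carbon <- generate_corpus(corpus_spec(20, type_distribution = c(C = 1),
                                        seed = 2))
  strategies <- list(random = list(strategy = "random", mask_ratio = 0.15),
                     wmm = list(strategy = "wmm", k = 0.9, mask_ratio = 0.15))
  rep1 <- mask_distribution_report(carbon, strategies, n_epochs = 3, seed = 1)
  expect_equal(rep1$element, "C")
  expect_equal(rep1$random, 1)
  expect_equal(rep1$wmm, 1)

  corpus <- toy_corpus(60L, seed = 101L)
  rep2 <- mask_distribution_report(corpus, strategies, n_epochs = 2, seed = 1)
  expect_equal(sum(rep2$random), 1, tolerance = 1e-12)
  expect_equal(sum(rep2$wmm), 1, tolerance = 1e-12)
  tf <- attr(rep2, "trace_fraction")
  expect_named(tf, c("random", "wmm"))
  expect_gt(attr(rep2, "trace_ratio")[["wmm"]], 1)
})
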