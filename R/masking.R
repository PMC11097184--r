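# Frequency-weighted atom masking (WMM).
#
# Each atom's masking weight depends on how many atoms of the same element
# its molecule contains: w = ln(k * (n + 1)) / n for within-molecule count
# n and hyperparameter k. The weight decreases in n, so rare ("trace")
# elements such as halogens are masked more often than under uniform random
# masking, while the expected number of masked atoms per element,
# M * ln(k(n+1)) / sum_beta ln(k(n_beta+1)), still grows with n: many
# high-frequency atoms are masked in absolute terms even though each one
# individually carries a low weight. Selection without replacement uses the
# exponential-keys scheme (Efraimidis & Spirakis), which realizes sequential
# probability-proportional-to-remaining-weight sampling.

#' Count atoms per element within one molecule
#'
#' @param mol A [mol_graph()].
#' @return Object of class `type_counts`: list with `counts` (named integer
#'   vector, element symbol -> within-molecule count, in first-occurrence
#'   order) and `total` (N, the atom count).
#' @export
#' @examples
#' count_atom_types(parse_smiles("CCO"))$counts  # C 2, O 1
count_atom_types <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  syms <- mol$atoms$symbol
  counts <- table(factor(syms, levels = unique(syms)))
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 total = length(syms)),
            class = "type_counts")
}

#' WMM masking weight of an atom type
#'
#' `w = ln(k * (n + 1)) / n`, strictly positive and strictly decreasing in
#' the within-molecule count `n` for `k >= 0.8`. Larger `k` raises the
#' weight of rare types much more than that of frequent types.
#'
#' @param n Within-molecule count of the atom's element (positive integer,
#'   vectorized).
#' @param k Rarity-emphasis hyperparameter; `k >= 0.8` guarantees a
#'   positive weight at `n = 1`.
#' @return Numeric weight(s).
#' @export
#' @examples
#' atom_weight(1, 1.0)  # log(2)
atom_weight <- function(n, k) {
  stopifnot(is.numeric(n), length(n) >= 1L, all(n >= 1), all(n == floor(n)),
            is.numeric(k), length(k) == 1L)
  if (any(k * (n + 1) <= 1)) {
    stop("k*(n+1) <= 1: masking weight would be non-positive (need k >= 0.8)")
  }
  log(k * (n + 1)) / n
}

#' Expected number of masked atoms per element
#'
#' For a mask budget of `M` atoms, the expected count for an element with
#' within-molecule count `n_a` is
#' `m_a = M * n_a * w_a / sum_b n_b * w_b = M * ln(k(n_a+1)) / sum_b ln(k(n_b+1))`.
#' The expectations sum exactly to `M` and increase with `n_a`: frequent
#' elements still receive most of the masks, just less disproportionately
#' than under uniform masking.
#'
#' @param tc A `type_counts` object (or named integer vector of counts).
#' @param M Mask budget (number of atoms to mask), `1 <= M <= N`.
#' @param k Rarity-emphasis hyperparameter.
#' @return Named numeric vector of expected masked counts per element.
#' @export
#' @examples
#' expected_masked_counts(count_atom_types(parse_smiles("CCO")), M = 1, k = 1)
expected_masked_counts <- function(tc, M, k) {
  counts <- if (inherits(tc, "type_counts")) tc$counts else tc
  stopifnot(is.numeric(counts), length(counts) >= 1L, all(counts >= 1))
  N <- sum(counts)
  if (M > N) stop("mask budget M = ", M, " exceeds atom count N = ", N)
  if (M < 1L) stop("mask budget M must be at least 1")
  terms <- log(k * (counts + 1))  # = n * atom_weight(n, k)
  M * terms / sum(terms)
}

#' Masking configuration for the weighted sampler
#'
#' @param k Rarity-emphasis hyperparameter; validated to `[0.8, 1.2]`, the
#'   range in which higher-frequency atoms are guaranteed lower weights
#'   without over-masking trace elements. Pass `unsafe = TRUE` to explore
#'   values outside it.
#' @param mask_ratio Fraction of each molecule's atoms to mask, in (0, 1].
#' @param seed Integer seed controlling the sampler.
#' @param unsafe Allow `k` outside `[0.8, 1.2]` (still requires `k > 0.5`
#'   so weights stay positive for all `n >= 1`).
#' @return Object of class `wmm_config`.
#' @export
wmm_config <- function(k = 0.9, mask_ratio = 0.15, seed = 0L, unsafe = FALSE) {
  stopifnot(is.numeric(k), length(k) == 1L,
            is.numeric(mask_ratio), mask_ratio > 0, mask_ratio <= 1)
  if (!unsafe && (k < 0.8 || k > 1.2)) {
    stop("k = ", k, " outside the validated range [0.8, 1.2]; ",
         "use unsafe = TRUE to override")
  }
  if (k <= 0.5) stop("k <= 0.5 gives non-positive weights at n = 1")
  structure(list(k = k, mask_ratio = mask_ratio, seed = as.integer(seed)),
            class = "wmm_config")
}

# Mask budget: round-half-up, at least one atom, at most N.
mask_budget <- function(mask_ratio, N) {
  max(1L, min(N, as.integer(floor(mask_ratio * N + 0.5))))
}

# Per-atom WMM weights for a molecule: every atom of one element shares the
# weight of that element's within-molecule count.
per_atom_weights <- function(mol, k) {
  tc <- count_atom_types(mol)
  w_type <- atom_weight(tc$counts, k)
  unname(w_type[mol$atoms$symbol])
}

new_mask_plan <- function(masked, weights, strategy) {
  structure(list(masked_indices = as.integer(sort(masked)),
                 M = length(masked),
                 per_atom_weight = weights,
                 strategy = strategy),
            class = "mask_plan")
}

# Vectorized exponential-keys draws: n_draws index sets of size M drawn
# without replacement with selection pressure proportional to `weights`.
# key_i = u_i^(1/w_i); the M largest keys win; ties break to the lower atom
# index. Returns an n_draws x M integer matrix. Consumes n_draws * N
# uniforms from the current RNG stream, row-major in atom order.
wmm_draw_many <- function(weights, M, n_draws) {
  N <- length(weights)
  U <- matrix(stats::runif(n_draws * N), nrow = n_draws, byrow = TRUE)
  K <- sweep(log(U), 2, weights, "/")  # log-keys: log(u)/w, same ordering
  sel <- matrix(0L, nrow = n_draws, ncol = M)
  for (m in seq_len(M)) {
    idx <- max.col(K, ties.method = "first")
    sel[, m] <- idx
    K[cbind(seq_len(n_draws), idx)] <- -Inf
  }
  sel
}

#' Select atoms to mask by weighted random sampling (WMM)
#'
#' Draws `M = max(1, round(mask_ratio * N))` distinct atoms without
#' replacement, each atom's selection pressure proportional to its WMM
#' weight ([atom_weight()] of its element's within-molecule count).
#' Implemented with exponential keys: `u_i^(1/w_i)` for
#' `u_i ~ Uniform(0,1)`, keeping the `M` largest keys (ties to the lower
#' atom index), which is equivalent to sequential
#' probability-proportional-to-remaining-weight sampling.
#'
#' @param mol A [mol_graph()].
#' @param cfg A [wmm_config()].
#' @param seed Optional integer; when supplied, the draw happens in a local
#'   RNG scope seeded with it. When NULL (default), uniforms are consumed
#'   from the current RNG stream, so callers can manage reproducibility.
#' @return A `mask_plan`: `masked_indices` (sorted, 1-based), `M`,
#'   `per_atom_weight`, `strategy = "wmm"`.
#' @export
sample_mask_wmm <- function(mol, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "wmm_config"))
  N <- n_atoms(mol)
  w <- per_atom_weights(mol, cfg$k)
  M <- mask_budget(cfg$mask_ratio, N)
  draw <- function() wmm_draw_many(w, M, 1L)[1L, ]
  masked <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_mask_plan(masked, w, "wmm")
}

#' Select atoms to mask uniformly at random
#'
#' The random-masking baseline: a uniform `M`-subset of atoms,
#' `M = max(1, round(mask_ratio * N))`.
#'
#' @param mol A [mol_graph()].
#' @param mask_ratio Fraction of atoms to mask, in (0, 1].
#' @param seed Optional integer for a local RNG scope (see
#'   [sample_mask_wmm()]).
#' @return A `mask_plan` with `strategy = "random"`.
#' @export
sample_mask_random <- function(mol, mask_ratio = 0.15, seed = NULL) {
  N <- n_atoms(mol)
  M <- mask_budget(mask_ratio, N)
  draw <- function() sample.int(N, M)
  masked <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_mask_plan(masked, rep(1, N), "random")
}

#' Exact inclusion probabilities of sequential weighted sampling
#'
#' Brute-force oracle for the weighted sampler: enumerates every ordered
#' without-replacement draw of length `M` under sequential selection with
#' probability proportional to the remaining weights, and accumulates exact
#' per-atom inclusion probabilities. Factorial in `N`, hence refused for
#' `N > 8`.
#'
#' @param weights Positive per-atom weights (N <= 8).
#' @param M Number of atoms drawn, `1 <= M <= N`.
#' @return Numeric vector of per-atom inclusion probabilities; sums to `M`.
#' @export
#' @examples
#' inclusion_probabilities_bruteforce(c(1, 1, 2), 1)  # 0.25 0.25 0.50
inclusion_probabilities_bruteforce <- function(weights, M) {
  N <- length(weights)
  if (N > 8L) stop("refusing factorial enumeration for N > 8")
  stopifnot(all(weights > 0), M >= 1L, M <= N)
  prob <- numeric(N)
  recurse <- function(remaining, p_path, depth) {
    total <- sum(weights[remaining])
    for (i in remaining) {
      p <- p_path * weights[i] / total
      prob[i] <<- prob[i] + p
      if (depth < M) {
        recurse(setdiff(remaining, i), p, depth + 1L)
      }
    }
  }
  recurse(seq_len(N), 1, 1L)
  prob
}

#' Corrupt graph tensors according to a mask plan
#'
#' Replaces the atom-type index of every masked node by the reserved mask
#' token and resets its chirality to "unspecified"; edges and unmasked
#' nodes are untouched. The input is not modified in place.
#'
#' @param gt A `graph_tensors` object from [featurize()].
#' @param plan A `mask_plan`.
#' @return List with `corrupted` (new `graph_tensors`) and `targets`
#'   (named integer vector: original atom-type indices at the masked
#'   positions, names = node indices).
#' @export
apply_mask <- function(gt, plan) {
  stopifnot(inherits(gt, "graph_tensors"), inherits(plan, "mask_plan"))
  idx <- plan$masked_indices
  if (any(idx < 1L | idx > gt$n_nodes)) {
    stop("mask plan indices out of range for these tensors")
  }
  vocab <- feature_vocab()
  targets <- stats::setNames(gt$node_features[idx, "atom_type"], idx)
  corrupted <- gt
  corrupted$node_features[idx, "atom_type"] <- vocab$mask_token
  corrupted$node_features[idx, "chirality"] <- 1L  # unspecified
  list(corrupted = corrupted, targets = targets)
}

#' Masked-element distribution under different masking strategies
#'
#' Replays masking over a corpus for several epochs per strategy and
#' tabulates which elements end up masked — the diagnostic contrast between
#' uniform random masking (mostly carbon) and WMM (trace elements enriched).
#'
#' @param corpus List of `mol_graph`s.
#' @param strategies Named list of strategy configs; each element is either
#'   `list(strategy = "random", mask_ratio =)` or
#'   `list(strategy = "wmm", k =, mask_ratio =)`.
#' @param n_epochs Number of independent masking rounds over the corpus.
#' @param seed Integer seed (one RNG stream for the whole report).
#' @param trace_elements Elements counted as "trace" for the enrichment
#'   ratio.
#' @return A data frame with columns `element`, one masked-fraction column
#'   per strategy (each column sums to 1). Attribute `trace_fraction` holds
#'   the per-strategy trace-element masked fraction, and `trace_ratio` the
#'   ratio of every strategy's trace fraction to that of strategy
#'   "random" (when present).
#' @export
mask_distribution_report <- function(corpus, strategies, n_epochs = 1L,
                                     seed = 0L,
                                     trace_elements = c("S", "F", "Cl", "Br", "I")) {
  stopifnot(length(corpus) > 0L, length(strategies) >= 1L)
  if (is.null(names(strategies)) || any(!nzchar(names(strategies)))) {
    stop("strategies must be a named list")
  }
  elements <- sort(unique(unlist(lapply(corpus, function(m) m$atoms$symbol))))
  tallies <- withr::with_seed(as.integer(seed), {
    lapply(strategies, function(scfg) {
      tally <- stats::setNames(numeric(length(elements)), elements)
      for (epoch in seq_len(n_epochs)) {
        for (mol in corpus) {
          plan <- if (identical(scfg$strategy, "wmm")) {
            cfg <- wmm_config(k = scfg$k %||% 0.9,
                              mask_ratio = scfg$mask_ratio %||% 0.15)
            sample_mask_wmm(mol, cfg)
          } else {
            sample_mask_random(mol, scfg$mask_ratio %||% 0.15)
          }
          masked_sym <- mol$atoms$symbol[plan$masked_indices]
          cnt <- table(factor(masked_sym, levels = elements))
          tally <- tally + as.numeric(cnt)
        }
      }
      tally / sum(tally)
    })
  })
  report <- data.frame(element = elements, stringsAsFactors = FALSE)
  for (nm in names(tallies)) report[[nm]] <- as.numeric(tallies[[nm]])
  trace_frac <- vapply(tallies, function(t) {
    sum(t[names(t) %in% trace_elements])
  }, numeric(1))
  attr(report, "trace_fraction") <- trace_frac
  if ("random" %in% names(trace_frac) && trace_frac[["random"]] > 0) {
    attr(report, "trace_ratio") <- trace_frac / trace_frac[["random"]]
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
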