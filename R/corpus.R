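# Synthetic molecule corpus with an imbalanced, drug-like atom-type
# distribution: carbon ~74% of heavy atoms, C+N+O ~96%, trace elements
# (S, F, Cl, Br) ~4%. Molecules are assembled as valence-respecting
# skeletons (tree + optional ring closures) decorated with heteroatoms, so
# every emitted molecule is chemically valid and round-trips through its
# SMILES. A small fraction of "burst" molecules concentrate trace elements,
# so that within those molecules a halogen can outnumber oxygen or
# nitrogen even though it is globally rare.

#' Specification of a synthetic molecule corpus
#'
#' @param n_molecules Number of molecules to generate.
#' @param atom_budget Length-2 integer vector: (min, max) heavy atoms per
#'   molecule; drawn uniformly.
#' @param type_distribution Named numeric vector of target global atom-type
#'   frequencies; must sum to 1 (within 1e-9). Default mirrors a drug-like
#'   library: C 0.74, O 0.12, N 0.10, trace 0.04.
#' @param trace_elements Elements treated as trace for burst decoration and
#'   reporting.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return Object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_molecules,
                        atom_budget = c(10L, 30L),
                        type_distribution = c(C = 0.74, O = 0.12, N = 0.10,
                                              S = 0.013, F = 0.012,
                                              Cl = 0.012, Br = 0.003),
                        trace_elements = c("S", "F", "Cl", "Br"),
                        seed = 0L) {
  stopifnot(n_molecules >= 1L, length(atom_budget) == 2L,
            atom_budget[1] >= 1L, atom_budget[2] >= atom_budget[1])
  if (abs(sum(type_distribution) - 1) > 1e-9) {
    stop("type_distribution must sum to 1")
  }
  if (is.null(names(type_distribution))) stop("type_distribution must be named")
  atomic_number(names(type_distribution))  # validate symbols
  unknown_val <- setdiff(names(type_distribution), names(ORGANIC_VALENCE))
  if (length(unknown_val) > 0L) {
    stop("no valence model for element(s): ", paste(unknown_val, collapse = ", "))
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 atom_budget = as.integer(atom_budget),
                 type_distribution = type_distribution,
                 trace_elements = trace_elements,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# Largest-remainder apportionment of `total` atoms to the target frequencies.
apportion_counts <- function(freq, total) {
  raw <- freq * total
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(freq))
}

# Draw one molecule's element composition from the shared urn. Feasibility:
# at least one multivalent atom, and enough spare valence on the tree
# skeleton to host every monovalent atom.
draw_composition <- function(urn, n_atoms, boost) {
  comp <- stats::setNames(integer(length(urn)), names(urn))
  pool <- urn
  for (j in seq_len(n_atoms)) {
    w <- pool * boost[names(pool)]
    if (j == 1L && pool[["C"]] > 0L) {
      pick <- "C"  # seed the skeleton with a carbon when available
    } else {
      if (sum(w) <= 0) return(NULL)
      pick <- sample(names(pool), 1L, prob = w)
    }
    comp[pick] <- comp[pick] + 1L
    pool[pick] <- pool[pick] - 1L
  }
  val <- ORGANIC_VALENCE[names(comp)]
  n_mono <- sum(comp[val == 1L])
  n_multi <- n_atoms - n_mono
  if (n_multi < 1L && n_atoms > 1L) return(NULL)
  spare <- sum((comp * val)[val > 1L]) - 2L * max(0L, n_multi - 1L)
  if (spare < n_mono) return(NULL)
  comp
}

# Assemble a valence-respecting molecular graph from an element composition:
# random tree over multivalent atoms, monovalent atoms attached to spare
# valence, optional ring closures and one carbonyl upgrade.
build_molecule <- function(comp) {
  symbols <- rep(names(comp), comp)
  val <- unname(ORGANIC_VALENCE[symbols])
  multi <- which(val > 1L)
  mono <- which(val == 1L)
  # carbons first so the DFS root is (usually) carbon, rest shuffled
  multi <- multi[order(symbols[multi] != "C", stats::runif(length(multi)))]
  ord <- c(multi, mono[order(stats::runif(length(mono)))])
  symbols <- symbols[ord]
  val <- val[ord]
  n <- length(symbols)
  nm <- length(multi)
  deg <- integer(n)
  edges <- matrix(integer(0), ncol = 2)
  add_edge <- function(u, v) {
    edges <<- rbind(edges, c(u, v))
    deg[u] <<- deg[u] + 1L
    deg[v] <<- deg[v] + 1L
  }
  if (nm > 1L) {
    for (j in 2:nm) {
      hosts <- which(deg[seq_len(j - 1L)] < val[seq_len(j - 1L)])
      host <- if (length(hosts) == 1L) hosts else sample(hosts, 1L)
      add_edge(host, j)
    }
  }
  for (m in seq_along(symbols)[-seq_len(nm)]) {
    hosts <- which(deg[seq_len(nm)] < val[seq_len(nm)])
    if (length(hosts) == 0L) return(NULL)
    host <- if (length(hosts) == 1L) hosts else sample(hosts, 1L)
    add_edge(host, m)
  }
  bond_order <- rep(1L, nrow(edges))
  # ring closures between multivalent atoms with spare valence at tree
  # distance 2..6 (ring sizes 3..7)
  n_rings <- sample(0:2, 1L, prob = c(0.2, 0.5, 0.3))
  if (n_rings > 0L && nm >= 3L) {
    for (r in seq_len(n_rings)) {
      spare_atoms <- which(deg < val & seq_len(n) <= nm)
      if (length(spare_atoms) < 2L) break
      d <- graph_distances(n, edges)
      cand <- which(d[spare_atoms, spare_atoms, drop = FALSE] >= 2 &
                    d[spare_atoms, spare_atoms, drop = FALSE] <= 6,
                    arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      if (nrow(cand) == 0L) break
      pick <- cand[sample.int(nrow(cand), 1L), ]
      add_edge(spare_atoms[pick[1]], spare_atoms[pick[2]])
      bond_order <- c(bond_order, 1L)
    }
  }
  # occasionally upgrade a terminal C-O single bond to a carbonyl
  if (stats::runif(1) < 0.35) {
    term_o <- which(symbols == "O" & deg == 1L)
    for (o in term_o) {
      e <- which((edges[, 1] == o | edges[, 2] == o) & bond_order == 1L)[1]
      host <- setdiff(edges[e, ], o)
      if (symbols[host] == "C" && deg[host] < val[host]) {
        bond_order[e] <- 2L
        deg[o] <- deg[o] + 1L
        deg[host] <- deg[host] + 1L
        break
      }
    }
  }
  list(symbols = symbols, edges = edges, bond_order = bond_order)
}

# All-pairs shortest path lengths by BFS (small molecules only).
graph_distances <- function(n, edges) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (u in frontier) for (v in adj[[u]]) {
        if (is.infinite(d[s, v])) { d[s, v] <- d[s, u] + 1; nxt <- c(nxt, v) }
      }
      frontier <- nxt
    }
  }
  d
}

# Emit a SMILES string by DFS over the bond graph; non-tree edges become
# ring-closure digits. Only single/double bonds occur by construction, and
# all atoms respect organic-subset default valences, so bare atom symbols
# are valid.
emit_smiles <- function(symbols, edges, bond_order) {
  n <- length(symbols)
  if (n == 1L) return(symbols[1])
  adj <- lapply(seq_len(n), function(i) integer(0))
  eid <- new.env()
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
    assign(paste(min(u, v), max(u, v)), e, envir = eid)
  }
  bond_of <- function(u, v) get(paste(min(u, v), max(u, v)), envir = eid)
  visited <- rep(FALSE, n)
  tree_edge <- rep(FALSE, nrow(edges))
  order_visit <- integer(0)
  parent <- rep(NA_integer_, n)
  stack <- 1L
  visited[1L] <- TRUE
  while (length(stack) > 0L) {  # iterative DFS, children in index order
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order_visit <- c(order_visit, v)
    kids <- adj[[v]][!visited[adj[[v]]]]
    for (u in rev(kids)) {
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        tree_edge[bond_of(v, u)] <- TRUE
        stack <- c(stack, u)
      }
    }
  }
  ring_edges <- which(!tree_edge)
  ring_digit <- stats::setNames(seq_along(ring_edges), ring_edges)
  ring_at <- lapply(seq_len(n), function(i) integer(0))
  for (e in ring_edges) {
    ring_at[[edges[e, 1]]] <- c(ring_at[[edges[e, 1]]], ring_digit[[as.character(e)]])
    ring_at[[edges[e, 2]]] <- c(ring_at[[edges[e, 2]]], ring_digit[[as.character(e)]])
  }
  if (length(ring_edges) > 9L) stop("too many ring closures for digit labels")
  children <- lapply(seq_len(n), function(v) which(parent == v))
  bond_sym <- function(u, v) if (bond_order[bond_of(u, v)] == 2L) "=" else ""
  write_atom <- function(v) {
    tok <- paste0(symbols[v], paste(ring_at[[v]], collapse = ""))
    kids <- children[[v]]
    if (length(kids) == 0L) return(tok)
    parts <- vapply(kids, function(u) paste0(bond_sym(v, u), write_atom(u)), "")
    last <- length(parts)
    wrapped <- c(if (last > 1L) paste0("(", parts[-last], ")"), parts[last])
    paste0(tok, paste(wrapped, collapse = ""))
  }
  write_atom(1L)
}

#' Generate a synthetic molecule corpus
#'
#' Deterministic given `spec$seed`. Atom counts per molecule are uniform on
#' `atom_budget`; element compositions are drawn without replacement from a
#' global urn apportioned to `type_distribution`, so realized global
#' frequencies match the targets up to rounding. About 8% of molecules are
#' trace "bursts" (element draw odds for trace elements multiplied by 8),
#' reproducing molecules in which a globally rare element such as chlorine
#' outnumbers oxygen or nitrogen. Every molecule is a valence-respecting
#' graph that parses back from its own SMILES.
#'
#' @param spec A [corpus_spec()].
#' @param max_retries Per-molecule composition/assembly retries before the
#'   generator gives up with an error.
#' @return List of [mol_graph()]s of length `spec$n_molecules`, each with a
#'   `smiles` string and a `synth_<i>` name.
#' @export
generate_corpus <- function(spec, max_retries = 60L) {
  stopifnot(inherits(spec, "corpus_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_molecules
    budget <- seq(spec$atom_budget[1], spec$atom_budget[2])
    sizes <- budget[sample.int(length(budget), n, replace = TRUE)]
    urn <- apportion_counts(spec$type_distribution, sum(sizes))
    burst <- stats::runif(n) < 0.08
    boost_plain <- stats::setNames(rep(1, length(urn)), names(urn))
    boost_burst <- boost_plain
    boost_burst[names(boost_burst) %in% spec$trace_elements] <- 8
    corpus <- vector("list", n)
    for (i in seq_len(n)) {
      built <- NULL
      for (try in seq_len(max_retries)) {
        boost <- if (burst[i] && try <= max_retries / 2) boost_burst else boost_plain
        comp <- draw_composition(urn, sizes[i], boost)
        if (is.null(comp)) next
        built <- build_molecule(comp)
        if (!is.null(built)) {
          urn <- urn - comp
          break
        }
      }
      if (is.null(built)) {
        stop("could not assemble a valid molecule for spec after ",
             max_retries, " retries (infeasible distribution/budget?)")
      }
      smi <- emit_smiles(built$symbols, built$edges, built$bond_order)
      bonds <- data.frame(u = built$edges[, 1], v = built$edges[, 2],
                          type = ifelse(built$bond_order == 2L, "double", "single"),
                          dir = "none", stringsAsFactors = FALSE)
      corpus[[i]] <- mol_graph(built$symbols, bonds,
                               name = sprintf("synth_%05d", i), smiles = smi)
    }
    corpus
  })
}

#' Realized atom-type frequencies of a corpus
#'
#' @param corpus List of `mol_graph`s.
#' @return Named numeric vector of global element frequencies (sums to 1).
#' @export
corpus_type_frequencies <- function(corpus) {
  syms <- unlist(lapply(corpus, function(m) m$atoms$symbol))
  tab <- table(syms)
  stats::setNames(as.numeric(tab) / length(syms), names(tab))
}

#' Attach synthetic binary property labels to a corpus
#'
#' Labels molecules by simple structural rules (presence of a trace
#' element; two or more rings; heteroatom-rich; presence of a double
#' bond), then flips a fraction of labels (noise) and blanks a fraction
#' (missing values), emulating a multi-task property-prediction dataset.
#' These labels are synthetic: they are learnable from structure but carry
#' no real pharmacology.
#'
#' @param corpus List of `mol_graph`s.
#' @param n_tasks Number of label columns (1..4).
#' @param noise Probability of flipping each observed label.
#' @param missing_rate Probability that a label is missing (`NA`).
#' @param seed Integer seed.
#' @return An `n x n_tasks` integer matrix of 0/1/NA labels.
#' @export
attach_synthetic_labels <- function(corpus, n_tasks = 2L, noise = 0.1,
                                    missing_rate = 0.1, seed = 0L) {
  stopifnot(n_tasks >= 1L, n_tasks <= 4L)
  rules <- list(
    function(m) any(m$atoms$symbol %in% c("S", "F", "Cl", "Br", "I")),
    function(m) nrow(m$bonds) >= n_atoms(m) + 1L,  # cyclomatic number >= 2
    function(m) sum(m$atoms$symbol %in% c("N", "O")) >= 4L,
    function(m) any(m$bonds$type == "double")
  )
  withr::with_seed(as.integer(seed), {
    labels <- sapply(seq_len(n_tasks), function(t) {
      y <- vapply(corpus, function(m) as.integer(rules[[t]](m)), 1L)
      flip <- stats::runif(length(y)) < noise
      y[flip] <- 1L - y[flip]
      y[stats::runif(length(y)) < missing_rate] <- NA_integer_
      y
    })
    matrix(labels, ncol = n_tasks,
           dimnames = list(NULL, paste0("task", seq_len(n_tasks))))
  })
}
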