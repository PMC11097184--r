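# Packaged worked examples: two stand-in molecules with the qualitative
# structure the masking analysis argues from, the default imbalanced corpus
# specification, and a tagged expected-values table.

MOL1_SMILES <- "CC(N)Cc1ccccc1F"
MOL2_SMILES <- "CC(=O)Nc1ccc(Cl)c(Cl)c1Cl"

#' Stand-in example molecule 1 (phenyl ring, a single fluorine)
#'
#' A fixed literal molecule whose masking behaviour illustrates the cost of
#' masking a unique trace atom: it contains a phenyl ring and exactly one
#' fluorine, so masking that fluorine removes the only atom of its type
#' from the molecule's semantics. Synthetic stand-in: chosen for these
#' qualitative properties, not taken from any external dataset.
#'
#' @return A [mol_graph()].
#' @export
mol1_standin <- function() parse_smiles(MOL1_SMILES, name = "mol1_standin")

#' Stand-in example molecule 2 (phenyl, carbonyl, chlorine-heavy)
#'
#' A fixed literal molecule whose within-molecule atom distribution deviates
#' from the global one: it contains a phenyl group, a carbonyl group, and
#' more chlorine atoms than oxygen and than nitrogen atoms, even though
#' chlorine is globally a trace element. Synthetic stand-in (see
#' [mol1_standin()]).
#'
#' @return A [mol_graph()].
#' @export
mol2_standin <- function() parse_smiles(MOL2_SMILES, name = "mol2_standin")

#' Default imbalanced corpus specification
#'
#' The corpus conditions the synthetic generator emulates: carbon 74% of
#' heavy atoms, oxygen + nitrogen 22%, trace elements (S, F, Cl, Br) 4% in
#' total.
#'
#' @param n_molecules Number of molecules (default 500).
#' @param seed Integer seed.
#' @return A [corpus_spec()].
#' @export
imbalanced_corpus_spec <- function(n_molecules = 500L, seed = 0L) {
  corpus_spec(n_molecules = n_molecules, seed = seed)
}

#' Load the packaged expected-values table
#'
#' A flat tagged table of worked-example expectations shipped with the
#' package; every row carries a provenance tag (PAPER, TRIVIAL or DERIVED)
#' and, for DERIVED rows, the oracle that produced the value.
#'
#' @return Data frame with columns `case`, `operation`, `expected`, `tag`,
#'   `oracle`.
#' @export
load_fixture_expectations <- function() {
  path <- system.file("extdata", "expected_values.tsv", package = "molmask")
  if (!nzchar(path)) stop("expected_values.tsv not found in installed package")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$tag), c("PAPER", "TRIVIAL", "DERIVED"))
  if (length(bad) > 0L) stop("unknown provenance tag(s): ", paste(bad, collapse = ", "))
  df
}
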