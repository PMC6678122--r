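# Bundled RNA folding engine: deterministic minimum-free-energy prediction
# restricted to single stem-loop structures (one terminal loop, no
# multibranching), with a nearest-neighbour stacking table and linear loop
# penalties. The restriction is what makes the model exactly enumerable and
# its output directly interpretable as a hairpin, which is the only
# structure class a pre-miRNA evaluation needs. External folders can be
# substituted behind fold()'s contract (a structure string plus an MFE).

#' Energy parameters of the bundled folding engine
#'
#' The stacking table is shipped as a plain-text fixture
#' (`stack_energies.tsv`); loop terms are linear in loop size.
#'
#' @param hairpin_a,hairpin_b terminal-loop penalty: `a + b * loop_size`
#'   (kcal/mol)
#' @param loop_a,loop_b bulge/interior-loop penalty: `a + b * unpaired_bases`
#' @param min_loop minimal terminal loop size (bases)
#' @param max_gap maximal unpaired bases per side between consecutive pairs
#' @param duplex_init initiation penalty for a bimolecular miRNA/target
#'   duplex (kcal/mol)
#' @return list of parameters including the 6x6 stacking matrix (`stack`),
#'   rows/columns ordered AU, UA, GC, CG, GU, UG
#' @export
energy_model <- function(hairpin_a = 4.5, hairpin_b = 0.3,
                         loop_a = 2.0, loop_b = 0.5,
                         min_loop = 3L, max_gap = 3L,
                         duplex_init = 4.1) {
  list(stack = stack_table(), hairpin_a = hairpin_a, hairpin_b = hairpin_b,
       loop_a = loop_a, loop_b = loop_b, min_loop = as.integer(min_loop),
       max_gap = as.integer(max_gap), duplex_init = duplex_init)
}

stack_table <- function() {
  if (is.null(.seedmir$stack)) {
    df <- read_tsv(seedmir_extdata("stack_energies.tsv"))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1L]]
    stopifnot(identical(rownames(m), c("AU", "UA", "GC", "CG", "GU", "UG")),
              identical(colnames(m), rownames(m)))
    .seedmir$stack <- m
  }
  .seedmir$stack
}

#' Fold a sequence into its minimum-energy single stem-loop
#'
#' Finds the minimum-free-energy structure among all single stem-loops
#' (chains of nested base pairs with one terminal loop of at least
#' `min_loop` bases, bulges/interior loops up to `max_gap` bases per side,
#' Watson-Crick and G:U pairs). The open chain scores 0 kcal/mol, so the
#' reported MFE is never positive. Deterministic, including tie-breaks.
#'
#' @param sequence a single RNA/DNA string (U and T equivalent)
#' @param model energy parameters from [energy_model()]
#' @return list with `structure` (dot-bracket), `mfe` (kcal/mol) and
#'   `n_pairs`
#' @examples
#' fold(paste0(strrep("GC", 10), "TTTT", strrep("GC", 10)))$mfe
#' @export
fold <- function(sequence, model = energy_model()) {
  stopifnot(length(sequence) == 1L)
  res <- fold_engine(seq_to_int(sequence), model$stack,
                     model$hairpin_a, model$hairpin_b,
                     model$loop_a, model$loop_b,
                     model$min_loop, model$max_gap)
  res$sequence <- norm_seq(sequence)
  class(res) <- "seedmir_fold"
  res
}

#' @export
print.seedmir_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n",
      sprintf("MFE = %.2f kcal/mol (%d pairs)\n", x$mfe, x$n_pairs), sep = "")
  invisible(x)
}

# Paired partner for every position (0 = unpaired), from a dot-bracket
# string of a single stem (nesting makes a stack sufficient).
pair_map <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  n <- length(ch)
  partner <- integer(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      j <- open[length(open)]
      open <- open[-length(open)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(open)) stop("unbalanced dot-bracket structure")
  partner
}

# Arm geometry of a folded hairpin: indices of the outermost and innermost
# pairs. Returns NULL for an unpaired structure.
hairpin_extent <- function(structure) {
  partner <- pair_map(structure)
  paired <- which(partner > 0)
  if (!length(paired)) return(NULL)
  opens <- which(strsplit(structure, "")[[1L]] == "(")
  list(outer_i = min(paired), outer_j = max(paired),
       inner_i = max(opens), inner_j = partner[max(opens)],
       partner = partner)
}
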