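# Rule-based miRNA target prediction: ungapped antiparallel complementarity
# with positional rules and G:U wobble half-penalties, plus a duplex
# MFE-ratio filter against the perfect-complement duplex.

#' Target-rule options
#'
#' @param max_score maximum total penalty (mismatch 1, G:U wobble 0.5)
#' @param max_seed_score maximum summed penalty over positions 1-12
#' @param max_adjacent longest allowed run of consecutive full mismatches
#' @param gu_ok_1011 whether a G:U wobble is tolerated at positions 10-11
#'   (full mismatches never are)
#' @param min_ratio minimum duplex MFE as a percentage of the
#'   perfect-complement duplex MFE
#' @return list of options
#' @export
target_rules <- function(max_score = 4, max_seed_score = 2.5,
                         max_adjacent = 2L, gu_ok_1011 = TRUE,
                         min_ratio = 75) {
  list(max_score = max_score, max_seed_score = max_seed_score,
       max_adjacent = as.integer(max_adjacent), gu_ok_1011 = gu_ok_1011,
       min_ratio = min_ratio)
}

# per-position pair state between miRNA position k (1 = 5' end) and the
# antiparallel target window: "match", "GU" or "mismatch"
site_states <- function(mirna, window) {
  m <- strsplit(norm_seq(mirna), "")[[1L]]
  w <- strsplit(norm_seq(window), "")[[1L]]
  if (length(m) != length(w)) stop("window length must equal miRNA length")
  t <- rev(w)
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(wc[m] == t, "match",
         ifelse((m == "G" & t == "T") | (m == "T" & t == "G"),
                "GU", "mismatch"))
}

#' Score one candidate target site
#'
#' Classifies every duplex position (miRNA 5' end = position 1) as
#' Watson-Crick match (penalty 0), G:U wobble (0.5) or mismatch (1) and
#' applies the rules: total penalty cap, no long mismatch runs, no
#' adjacent mismatches in positions 2-12, no mismatches at positions
#' 10-11, a penalty cap over positions 1-12, and the duplex MFE-ratio
#' floor.
#'
#' @param mirna miRNA sequence (5'->3')
#' @param window same-length target window (mRNA sense strand, 5'->3')
#' @param rules from [target_rules()]
#' @param model energy parameters from [energy_model()]
#' @return list: `states`, `score`, `seed_score`, `duplex_mfe`,
#'   `perfect_mfe`, `mfe_ratio`, `pass`, `failed` (names of violated rules)
#' @export
score_site <- function(mirna, window, rules = target_rules(),
                       model = energy_model()) {
  st <- site_states(mirna, window)
  pen <- c(match = 0, GU = 0.5, mismatch = 1)[st]
  score <- sum(pen)
  seed <- sum(pen[1:12])
  mm <- st == "mismatch"
  runs <- rle(mm)
  maxrun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  adj_seed <- any(mm[2:11] & mm[3:12])
  failed <- character(0)
  if (score > rules$max_score) failed <- c(failed, "max_score")
  if (maxrun > rules$max_adjacent) failed <- c(failed, "adjacent")
  if (adj_seed) failed <- c(failed, "adjacent_2_12")
  if (any(mm[10:11])) failed <- c(failed, "pos_10_11")
  if (!rules$gu_ok_1011 && any(st[10:11] == "GU"))
    failed <- c(failed, "pos_10_11")
  if (seed > rules$max_seed_score) failed <- c(failed, "seed_score")
  d <- duplex_mfe(mirna, window, model)
  ratio <- 100 * d$duplex_mfe / d$perfect_mfe
  if (ratio < rules$min_ratio) failed <- c(failed, "mfe_ratio")
  list(states = st, score = score, seed_score = seed,
       duplex_mfe = d$duplex_mfe, perfect_mfe = d$perfect_mfe,
       mfe_ratio = ratio, pass = !length(failed), failed = unique(failed))
}

#' Duplex minimum free energy of a miRNA bound to a target window
#'
#' Energy = duplex initiation + stacking energies summed over runs of
#' consecutive paired positions (Watson-Crick or G:U); mismatches
#' interrupt stacking. The perfect-complement duplex is evaluated
#' identically against the miRNA's exact reverse complement.
#'
#' @inheritParams score_site
#' @return list with `duplex_mfe` and `perfect_mfe` (kcal/mol)
#' @export
duplex_mfe <- function(mirna, window, model = energy_model()) {
  st <- site_states(mirna, window)
  m <- strsplit(norm_seq(mirna), "")[[1L]]
  t <- rev(strsplit(norm_seq(window), "")[[1L]])
  ptype <- ifelse(st == "mismatch", NA, paste0(chartr("T", "U", m),
                                               chartr("T", "U", t)))
  S <- model$stack
  e <- model$duplex_init
  for (k in seq_len(length(m) - 1L))
    if (!is.na(ptype[k]) && !is.na(ptype[k + 1L]))
      e <- e + S[ptype[k], ptype[k + 1L]]
  wc <- c(A = "AU", C = "CG", G = "GC", T = "UA")
  perfect <- model$duplex_init
  pp <- wc[m]
  for (k in seq_len(length(m) - 1L)) perfect <- perfect + S[pp[k], pp[k + 1L]]
  list(duplex_mfe = e, perfect_mfe = perfect)
}

#' Scan a transcriptome for miRNA target sites
#'
#' Every window of miRNA length on the sense strand of every unigene is
#' evaluated under [target_rules()]; all passing sites are reported.
#' Coordinates are 1-based inclusive on the unigene.
#'
#' @param mirnas named character vector of miRNA sequences (names = ids)
#' @param transcriptome unigene sequences (`DNAStringSet` or named
#'   character vector)
#' @param rules from [target_rules()]
#' @param model energy parameters
#' @return data frame: mirna_id, unigene, start, end, score, duplex_mfe,
#'   perfect_mfe, mfe_ratio, pairing (`|` match, `o` G:U, `.` mismatch,
#'   written 5'->3' along the miRNA)
#' @export
scan_targets <- function(mirnas, transcriptome, rules = target_rules(),
                         model = energy_model()) {
  stopifnot(!is.null(names(mirnas)))
  unis <- as_seq_vec(transcriptome)
  stopifnot(!is.null(names(unis)))
  rows <- list()
  for (mi in seq_along(mirnas)) {
    mir_int <- seq_to_int(mirnas[[mi]])
    for (ui in seq_along(unis)) {
      if (nchar(unis[[ui]]) < length(mir_int)) next
      hit <- scan_engine(mir_int, seq_to_int(unis[[ui]]), model$stack,
                         model$duplex_init, rules$max_score,
                         rules$max_seed_score, rules$max_adjacent,
                         rules$gu_ok_1011, rules$min_ratio)
      if (!length(hit$start)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = names(mirnas)[mi], unigene = names(unis)[ui],
        start = hit$start, end = hit$start + length(mir_int) - 1L,
        score = hit$score, duplex_mfe = hit$duplex_mfe,
        perfect_mfe = hit$perfect_mfe, mfe_ratio = hit$ratio,
        pairing = hit$pairing, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(0), unigene = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), duplex_mfe = numeric(0),
                      perfect_mfe = numeric(0), mfe_ratio = numeric(0),
                      pairing = character(0), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-miRNA target gene counts
#'
#' A gene counts once per miRNA regardless of site multiplicity;
#' co-targeting (several miRNAs hitting one gene) is preserved.
#'
#' @param sites site table from [scan_targets()]
#' @return data frame: mirna_id, n_target_genes
#' @export
target_gene_counts <- function(sites) {
  u <- unique(sites[, c("mirna_id", "unigene")])
  agg <- as.data.frame(table(u$mirna_id), stringsAsFactors = FALSE)
  names(agg) <- c("mirna_id", "n_target_genes")
  agg[order(-agg$n_target_genes, agg$mirna_id), , drop = FALSE]
}
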