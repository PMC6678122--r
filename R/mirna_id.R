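# Conserved miRNA matching, hairpin precursor recovery and evaluation
# (MFE/AMFE/MFEI), novel miRNA prediction under explicit hairpin criteria,
# and phase presence (Venn) partitioning.

#' Match clean tags against a mature plant miRNA reference
#'
#' A tag becomes a conserved miRNA record iff it is identical (zero
#' mismatches) to a reference mature sequence. The matched reference name
#' (miRBase style, e.g. `gma-miR156a-5p`) supplies the family and arm; ids
#' carry the `mpi-` species prefix. When one tag matches several reference
#' matures, the first in file order names the record and the others are
#' kept as synonyms.
#'
#' @param tags tag table from [collapse_tags()] (ncRNA-classified tags
#'   should be excluded first)
#' @param mature_ref `DNAStringSet` or named character vector of mature
#'   miRNA sequences (U or T)
#' @return data frame of conserved miRNA records with per-library counts
#' @export
match_conserved <- function(tags, mature_ref) {
  refs <- as_seq_vec(mature_ref)
  stopifnot(!is.null(names(refs)))
  hit <- match(tags$sequence, refs)
  idx <- which(!is.na(hit))
  libs <- setdiff(colnames(tags), c("sequence", "length", "total"))
  if (!length(idx)) {
    out <- data.frame(id = character(0), sequence = character(0),
                      family = character(0), arm = character(0),
                      origin = character(0), source_ref = character(0),
                      synonyms = character(0), stringsAsFactors = FALSE)
    for (l in libs) out[[l]] <- integer(0)
    out$total <- integer(0)
    return(out)
  }
  ref_name <- names(refs)[hit[idx]]
  fam_num <- regmatches(ref_name, regexpr("(?<=miR)[0-9]+", ref_name,
                                          perl = TRUE))
  family <- rep("unknown", length(idx))
  parsed <- grepl("miR[0-9]+", ref_name)
  if (any(!parsed))
    warning("reference name(s) without parsable miR family: ",
            paste(unique(ref_name[!parsed]), collapse = ", "))
  family[parsed] <- paste0("MIR", fam_num)
  arm <- ifelse(grepl("-5p$", ref_name), "5p",
                ifelse(grepl("-3p$", ref_name), "3p", NA))
  synonyms <- vapply(tags$sequence[idx], function(s) {
    alt <- names(refs)[refs == s]
    paste(alt[-1L], collapse = ",")
  }, character(1L), USE.NAMES = FALSE)
  out <- data.frame(
    id = paste0("mpi-", sub("^[a-z]{3,4}-", "", ref_name)),
    sequence = tags$sequence[idx], family = family, arm = arm,
    origin = "conserved", source_ref = ref_name, synonyms = synonyms,
    tags[idx, c(libs, "total"), drop = FALSE],
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$id), , drop = FALSE]
}

# Trim a folded window to its hairpin: the span of the outermost base pair,
# extended to contain the mature. Returns NULL when the mature does not sit
# in one arm (it overlaps the terminal loop or the structure is unpaired).
# AMFE = MFE / length * 100; MFEI = AMFE / GC%, with GC on the 0-100 scale.
trim_precursor <- function(window_seq, fold_result, mature_start, mature_end) {
  ext <- hairpin_extent(fold_result$structure)
  if (is.null(ext)) return(NULL)
  arm <- if (mature_end <= ext$inner_i) "5p"
         else if (mature_start >= ext$inner_j) "3p"
         else return(NULL)
  s <- min(ext$outer_i, mature_start)
  e <- max(ext$outer_j, mature_end)
  seqs <- substr(window_seq, s, e)
  partner <- ext$partner
  mpaired <- sum(partner[mature_start:mature_end] > 0L)
  len <- e - s + 1L
  gc <- gc_percent(seqs)
  amfe <- fold_result$mfe / len * 100
  list(start = s, end = e, sequence = seqs,
       structure = substr(fold_result$structure, s, e),
       mfe = fold_result$mfe, length = len, gc = gc, amfe = amfe,
       mfei = amfe / gc, arm = arm, mature_paired = mpaired,
       mature_unpaired = (mature_end - mature_start + 1L) - mpaired,
       loop_start = ext$inner_i + 1L, loop_end = ext$inner_j - 1L)
}

# Scan symmetric windows (60-300 nt, 20-nt steps) around a mature locus,
# fold each with the bundled engine, trim to the hairpin, and keep the
# qualifying window minimizing MFEI.
precursor_window <- function(unigene_seq, m_start, m_end,
                             model = energy_model(),
                             sizes = seq(60L, 300L, by = 20L)) {
  n <- nchar(unigene_seq)
  mid <- (m_start + m_end) / 2
  best <- NULL
  tried <- character(0)
  for (size in sizes) {
    ws <- max(1L, min(round(mid - size / 2), n - size + 1L))
    we <- min(n, ws + size - 1L)
    if (we - ws + 1L < 40L) next
    key <- paste(ws, we)
    if (key %in% tried) next
    tried <- c(tried, key)
    if (m_start < ws || m_end > we) next
    wseq <- substr(unigene_seq, ws, we)
    f <- fold(wseq, model)
    pr <- trim_precursor(wseq, f, m_start - ws + 1L, m_end - ws + 1L)
    if (is.null(pr)) next
    pr$start <- ws + pr$start - 1L
    pr$end <- ws + pr$end - 1L
    pr$loop_start <- ws + pr$loop_start - 1L
    pr$loop_end <- ws + pr$loop_end - 1L
    if (is.null(best) || pr$mfei < best$mfei) best <- pr
  }
  best
}

# total tag reads anchoring each arm of a precursor (tags fully contained
# in the arm, outside the terminal loop)
anchor_counts <- function(prec, tags) {
  hits <- which(stringi::stri_detect_fixed(prec$sequence, tags$sequence))
  a5 <- a3 <- 0
  arm5 <- c(prec$start, prec$loop_start - 1L)
  arm3 <- c(prec$loop_end + 1L, prec$end)
  for (h in hits) {
    pos <- stringi::stri_locate_all_fixed(prec$sequence,
                                          tags$sequence[h])[[1L]]
    for (r in seq_len(nrow(pos))) {
      st <- prec$start + pos[r, 1L] - 1L
      en <- prec$start + pos[r, 2L] - 1L
      if (st >= arm5[1L] && en <= arm5[2L]) { a5 <- a5 + tags$total[h]; break }
      if (st >= arm3[1L] && en <= arm3[2L]) { a3 <- a3 + tags$total[h]; break }
    }
  }
  c(anchored_reads_5p = a5, anchored_reads_3p = a3)
}

mirna_loci <- function(sequence, unigenes) {
  loc <- stringi::stri_locate_all_fixed(unigenes, sequence)
  hits <- which(!is.na(vapply(loc, function(m) m[1L, 1L], numeric(1L))))
  do.call(rbind, lapply(hits, function(h)
    data.frame(unigene = names(unigenes)[h], start = loc[[h]][, 1L],
               end = loc[[h]][, 2L], stringsAsFactors = FALSE)))
}

#' Recover hairpin precursors for conserved miRNAs from the transcriptome
#'
#' For every exact occurrence of a mature in a unigene, symmetric windows
#' of 60-300 nt are folded and trimmed to the hairpin; the window
#' minimizing MFEI with the mature inside one arm is kept, and the
#' precursor is accepted when more than `anchor_min` reads anchor the 5p
#' and/or the 3p arm.
#'
#' @param records conserved miRNA records from [match_conserved()]
#' @param tags tag table (used for arm-anchoring read counts)
#' @param transcriptome `DNAStringSet` or named character vector of unigenes
#' @param anchor_min anchoring read threshold (strictly more than this)
#' @param model energy parameters from [energy_model()]
#' @return data frame of precursors (coordinates 1-based inclusive,
#'   structure, MFE, AMFE, MFEI, arm-anchoring read counts)
#' @export
recover_precursors <- function(records, tags, transcriptome,
                               anchor_min = 10, model = energy_model()) {
  unis <- as_seq_vec(transcriptome)
  rows <- list()
  for (i in seq_len(nrow(records))) {
    loci <- mirna_loci(records$sequence[i], unis)
    if (is.null(loci)) next
    for (r in seq_len(nrow(loci))) {
      pr <- precursor_window(unis[[loci$unigene[r]]], loci$start[r],
                             loci$end[r], model)
      if (is.null(pr)) next
      anch <- anchor_counts(pr, tags)
      if (max(anch) <= anchor_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = records$id[i], unigene = loci$unigene[r],
        start = pr$start, end = pr$end, length = pr$length,
        gc = pr$gc, mfe = pr$mfe, amfe = pr$amfe, mfei = pr$mfei,
        arm = pr$arm, anchored_reads_5p = anch[["anchored_reads_5p"]],
        anchored_reads_3p = anch[["anchored_reads_3p"]],
        sequence = pr$sequence, structure = pr$structure,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(0), unigene = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), gc = numeric(0), mfe = numeric(0),
                      amfe = numeric(0), mfei = numeric(0), arm = character(0),
                      anchored_reads_5p = numeric(0),
                      anchored_reads_3p = numeric(0), sequence = character(0),
                      structure = character(0), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summary statistics of a precursor set
#'
#' Arithmetic means of length, GC%, MFE, AMFE and MFEI. The reported mean
#' MFEI is the mean of per-precursor MFEIs; the ratio of the mean AMFE to
#' the mean GC% is also returned (`mfei_of_means`) since the two summaries
#' differ in general.
#'
#' @param precursors precursor table from [recover_precursors()] or
#'   [predict_novel()]
#' @return one-row data frame of means
#' @export
precursor_stats <- function(precursors) {
  if (!nrow(precursors)) stop("empty precursor set")
  data.frame(n = nrow(precursors),
             mean_length = mean(precursors$length),
             mean_gc = mean(precursors$gc),
             mean_mfe = mean(precursors$mfe),
             mean_amfe = mean(precursors$amfe),
             mean_mfei = mean(precursors$mfei),
             mfei_of_means = mean(precursors$amfe) / mean(precursors$gc))
}

#' Criteria for novel miRNA prediction
#'
#' Explicit, configurable hairpin criteria in the spirit of the usual
#' transcriptome-based predictors: mature length bounds, minimum paired
#' mature bases (G:U counts as paired), maximum unpaired mature bases,
#' precursor MFE and MFEI ceilings, and a minimum total read count for a
#' tag to be considered at all.
#'
#' @param min_mature,max_mature mature length bounds (nt)
#' @param min_paired minimum mature bases paired in the hairpin
#' @param max_unpaired maximum unpaired mature bases
#' @param max_mfe precursor MFE ceiling (kcal/mol)
#' @param max_mfei precursor MFEI ceiling
#' @param min_count minimum total reads across libraries
#' @param min_anchor arm-anchoring read threshold (exclusive), as for
#'   conserved precursors: a hairpin only counts with more than this many
#'   reads anchoring its 5p and/or 3p arm
#' @return list of criteria
#' @export
novel_criteria <- function(min_mature = 18L, max_mature = 26L,
                           min_paired = 16L, max_unpaired = 4L,
                           max_mfe = -18, max_mfei = -0.85,
                           min_count = 5L, min_anchor = 10) {
  list(min_mature = min_mature, max_mature = max_mature,
       min_paired = min_paired, max_unpaired = max_unpaired,
       max_mfe = max_mfe, max_mfei = max_mfei, min_count = min_count,
       min_anchor = min_anchor)
}

#' Predict novel miRNAs from unannotated tags
#'
#' A tag becomes a novel miRNA iff it maps exactly to at least one unigene
#' whose surrounding window folds into a qualifying single stem-loop (see
#' [novel_criteria()]) with the mature inside one arm. Tags are considered
#' in order of decreasing total count (ties by sequence); ids are assigned
#' `mpi-nmiRNNNN-{5p,3p}` in that discovery order. A tag mapping to several
#' unigenes yields several precursor rows under one id.
#'
#' Hairpin loci are claimed greedily in tag-abundance order: once a
#' precursor interval is assigned (including any interval in `known_loci`,
#' typically the recovered conserved precursors), later tags mapping
#' inside it are treated as fragments or variants of that hairpin rather
#' than as independent novel miRNAs - one mature per locus, the way
#' transcriptome-based predictors resolve overlapping read clusters.
#'
#' @param tags tag table already excluding ncRNA-classified tags
#' @param transcriptome unigene sequences
#' @param exclude sequences excluded from prediction (known matures, i.e.
#'   anything matching the conserved reference)
#' @param criteria from [novel_criteria()]
#' @param model energy parameters
#' @param known_loci optional data frame (`unigene`, `start`, `end`) of
#'   already-claimed precursor intervals
#' @return list with `records` (novel miRNA records with per-library
#'   counts) and `precursors` (their hairpin table)
#' @export
predict_novel <- function(tags, transcriptome, exclude = character(0),
                          criteria = novel_criteria(),
                          model = energy_model(), known_loci = NULL) {
  unis <- as_seq_vec(transcriptome)
  libs <- setdiff(colnames(tags), c("sequence", "length", "total"))
  cand <- tags[tags$length >= criteria$min_mature &
               tags$length <= criteria$max_mature &
               tags$total >= criteria$min_count &
               !(tags$sequence %in% norm_seq(exclude)), , drop = FALSE]
  cand <- cand[order(-cand$total, cand$sequence), , drop = FALSE]
  occupied <- list()
  claim <- function(unigene, start, end) {
    occupied[[unigene]] <<- rbind(occupied[[unigene]], c(start, end))
  }
  is_claimed <- function(unigene, start, end) {
    iv <- occupied[[unigene]]
    !is.null(iv) && any(start <= iv[, 2L] & end >= iv[, 1L])
  }
  if (!is.null(known_loci) && nrow(known_loci))
    for (r in seq_len(nrow(known_loci)))
      claim(known_loci$unigene[r], known_loci$start[r], known_loci$end[r])
  recs <- list(); precs <- list(); serial <- 0L
  for (i in seq_len(nrow(cand))) {
    loci <- mirna_loci(cand$sequence[i], unis)
    if (is.null(loci)) next
    prs <- list()
    for (r in seq_len(nrow(loci))) {
      if (is_claimed(loci$unigene[r], loci$start[r], loci$end[r])) next
      pr <- precursor_window(unis[[loci$unigene[r]]], loci$start[r],
                             loci$end[r], model)
      if (is.null(pr)) next
      if (pr$mfe > criteria$max_mfe || pr$mfei > criteria$max_mfei) next
      if (pr$mature_paired < criteria$min_paired ||
          pr$mature_unpaired > criteria$max_unpaired) next
      anch <- anchor_counts(pr, tags)
      if (max(anch) <= criteria$min_anchor) next
      pr$anch <- anch
      pr$unigene <- loci$unigene[r]
      prs[[length(prs) + 1L]] <- pr
    }
    if (!length(prs)) next
    for (pr in prs) claim(pr$unigene, pr$start, pr$end)
    serial <- serial + 1L
    id <- sprintf("mpi-nmiR%04d-%s", serial, prs[[1L]]$arm)
    recs[[serial]] <- data.frame(
      id = id, sequence = cand$sequence[i], family = "novel",
      arm = prs[[1L]]$arm, origin = "novel", source_ref = NA_character_,
      synonyms = "", cand[i, c(libs, "total"), drop = FALSE],
      check.names = FALSE, stringsAsFactors = FALSE)
    for (pr in prs) {
      anch <- pr$anch
      precs[[length(precs) + 1L]] <- data.frame(
        mirna_id = id, unigene = pr$unigene, start = pr$start, end = pr$end,
        length = pr$length, gc = pr$gc, mfe = pr$mfe, amfe = pr$amfe,
        mfei = pr$mfei, arm = pr$arm,
        anchored_reads_5p = anch[["anchored_reads_5p"]],
        anchored_reads_3p = anch[["anchored_reads_3p"]],
        sequence = pr$sequence, structure = pr$structure,
        stringsAsFactors = FALSE)
    }
  }
  empty_rec <- data.frame(id = character(0), sequence = character(0),
                          family = character(0), arm = character(0),
                          origin = character(0), source_ref = character(0),
                          synonyms = character(0), stringsAsFactors = FALSE)
  for (l in c(libs, "total")) empty_rec[[l]] <- integer(0)
  list(records = if (length(recs))
         do.call(rbind, c(recs, list(make.row.names = FALSE))) else empty_rec,
       precursors = if (length(precs))
         do.call(rbind, c(precs, list(make.row.names = FALSE))) else
         recover_precursors(empty_rec[0, ], tags[0, ], character(0)))
}

#' Phase presence (Venn) partition of miRNAs
#'
#' A miRNA is present in a phase iff its reads summed over that phase's
#' replicates are at least `min_reads`. Returns the seven Venn region
#' counts, separately for conserved and novel records.
#'
#' @param records combined miRNA record table (conserved + novel)
#' @param min_reads presence threshold per phase (default 1 read)
#' @return data frame: region, conserved, novel; regions sum to the number
#'   of miRNAs present in at least one phase
#' @export
phase_presence <- function(records, min_reads = 1) {
  libs <- intersect(colnames(records), library_ids())
  ph <- phase_of(libs)
  pres <- vapply(levels(ph), function(p)
    rowSums(records[, libs[ph == p], drop = FALSE]) >= min_reads,
    logical(nrow(records)))
  pres <- matrix(pres, nrow = nrow(records),
                 dimnames = list(NULL, levels(ph)))
  regions <- list("I only" = c(TRUE, FALSE, FALSE),
                  "II only" = c(FALSE, TRUE, FALSE),
                  "III only" = c(FALSE, FALSE, TRUE),
                  "I&II" = c(TRUE, TRUE, FALSE),
                  "I&III" = c(TRUE, FALSE, TRUE),
                  "II&III" = c(FALSE, TRUE, TRUE),
                  "I&II&III" = c(TRUE, TRUE, TRUE))
  count_region <- function(rows, pat)
    sum(rows & pres[, 1L] == pat[1L] & pres[, 2L] == pat[2L] &
          pres[, 3L] == pat[3L])
  data.frame(
    region = names(regions),
    conserved = vapply(regions, function(p)
      count_region(records$origin == "conserved", p), numeric(1L)),
    novel = vapply(regions, function(p)
      count_region(records$origin == "novel", p), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}
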