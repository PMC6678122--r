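# Synthetic developing-seed small-RNA experiment with planted ground truth.
#
# The generator emits everything the pipeline consumes: a unigene
# transcriptome carrying planted hairpin precursors, a mature miRNA
# reference containing the planted conserved matures (and decoys), a
# contaminant ncRNA reference, GO/KEGG annotation tables with one enriched
# term per family planted by construction, and nine FASTQ libraries
# (3 developmental phases x 3 replicates) whose planted miRNAs follow
# designed phase trends.

TREND_CLASSES <- c("bell", "V", "up", "down",
                   "phaseI_only", "phaseII_only", "phaseIII_only", "flat")

trend_multipliers <- function(trend) {
  switch(trend,
    bell = c(1, 6, 1), V = c(6, 1, 6), up = c(1, 4, 12), down = c(12, 4, 1),
    phaseI_only = c(4, 0, 0), phaseII_only = c(0, 4, 0),
    phaseIII_only = c(0, 0, 4), flat = c(1, 1, 1),
    stop("unknown trend class '", trend, "'"))
}

default_profiles <- function(n_conserved, n_novel) {
  cons <- c("bell", "bell", "bell", "V", "V", "up", "up", "up",
            "down", "down", "down", "phaseI_only", "phaseI_only",
            "phaseII_only", "phaseII_only", "phaseIII_only",
            "flat", "flat", "flat", "flat")
  nov <- c("bell", "bell", "V", "up", "up", "down", "down",
           "phaseII_only", "phaseIII_only", "flat", "flat", "flat")
  c(rep_len(cons, length.out = n_conserved)[seq_len(n_conserved)],
    rep_len(nov, length.out = max(n_novel, 1L))[seq_len(n_novel)])
}

#' Configuration of the synthetic small-RNA experiment
#'
#' Defaults describe the emulated study design: nine libraries (three
#' phases, three replicates), 24-nt-dominant background with a
#' phase-dependent secondary length (21 nt in phase I, 22 nt later),
#' contaminant ncRNA fractions of 8/4/6% of clean reads in phases I/II/III,
#' and planted miRNAs whose per-phase mean counts follow designed trend
#' classes (bell, V, monotone, phase-exclusive, flat).
#'
#' @param rng_seed integer seed driving every random choice
#' @param n_unigenes number of transcriptome unigenes
#' @param unigene_length min/max unigene length (nt)
#' @param n_conserved_planted,n_novel_planted planted miRNA counts
#' @param n_decoy_reference extra mature-reference entries never planted
#' @param n_contaminant_species contaminant ncRNA records (cycled over
#'   rRNA/tRNA/snRNA/snoRNA classes)
#' @param phase_depths reads per library; length 1 or 9 (I-1..III-3)
#' @param adapter3,adapter5 adapter sequences ligated by the protocol
#' @param artifact_rates named fractions of reads emitted as artifacts:
#'   `no_adapter3`, `polyA`, `low_quality`, `too_short`; must sum below 1
#' @param contaminant_fraction fraction of clean reads drawn from the
#'   contaminant reference, per phase (named I/II/III)
#' @param base_abundance min/max expected clean reads per planted miRNA and
#'   library at the reference depth of 1e5 (scaled with depth)
#' @param replicate_sigma lognormal sigma of multiplicative replicate noise
#' @param profile_assignments optional character vector (length
#'   `n_conserved_planted + n_novel_planted`) of trend classes
#' @return validated config object of class `seedmir_sim_config`
#' @export
simulation_config <- function(rng_seed = 20190717L,
                              n_unigenes = 150L,
                              unigene_length = c(400L, 1500L),
                              n_conserved_planted = 20L,
                              n_novel_planted = 12L,
                              n_decoy_reference = 30L,
                              n_contaminant_species = 12L,
                              phase_depths = 1e5,
                              adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                              adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                              artifact_rates = c(no_adapter3 = 0.02,
                                                 polyA = 0.02,
                                                 low_quality = 0.03,
                                                 too_short = 0.02),
                              contaminant_fraction = c(I = 0.08, II = 0.04,
                                                       III = 0.06),
                              base_abundance = c(100, 600),
                              replicate_sigma = 0.15,
                              profile_assignments = NULL) {
  libs <- library_ids()
  if (length(phase_depths) == 1L) phase_depths <- rep(phase_depths, 9L)
  stopifnot(length(phase_depths) == 9L, all(phase_depths > 0))
  names(phase_depths) <- libs
  stopifnot(all(artifact_rates >= 0), all(artifact_rates <= 1),
            sum(artifact_rates) < 1,
            setequal(names(artifact_rates),
                     c("no_adapter3", "polyA", "low_quality", "too_short")),
            all(contaminant_fraction >= 0), all(contaminant_fraction < 1),
            setequal(names(contaminant_fraction), c("I", "II", "III")),
            n_conserved_planted >= 0, n_novel_planted >= 0,
            nchar(adapter3) >= 8, nchar(adapter5) >= 8)
  n_planted <- n_conserved_planted + n_novel_planted
  if (n_unigenes < n_planted + 20L)
    stop("n_unigenes must exceed the planted miRNA count by at least 20 ",
         "to leave room for target-site host genes")
  if (is.null(profile_assignments))
    profile_assignments <- default_profiles(n_conserved_planted,
                                            n_novel_planted)
  stopifnot(length(profile_assignments) == n_planted,
            all(profile_assignments %in% TREND_CLASSES))
  structure(list(rng_seed = as.integer(rng_seed),
                 n_unigenes = as.integer(n_unigenes),
                 unigene_length = as.integer(unigene_length),
                 n_conserved_planted = as.integer(n_conserved_planted),
                 n_novel_planted = as.integer(n_novel_planted),
                 n_decoy_reference = as.integer(n_decoy_reference),
                 n_contaminant_species = as.integer(n_contaminant_species),
                 phase_depths = phase_depths,
                 adapter3 = norm_seq(adapter3),
                 adapter5 = norm_seq(adapter5),
                 artifact_rates = artifact_rates,
                 contaminant_fraction = contaminant_fraction,
                 base_abundance = base_abundance,
                 replicate_sigma = replicate_sigma,
                 profile_assignments = profile_assignments),
            class = "seedmir_sim_config")
}

rand_seq <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

# a mature candidate with moderate GC so the planted hairpin is both stable
# and MFEI-typical
rand_mature <- function(len) {
  repeat {
    s <- rand_seq(len)
    gc <- gc_percent(s)
    if (gc >= 40 && gc <= 65) return(s)
  }
}

# hairpin core: mature in the designated arm, randomized terminal loop, and
# a near-reverse-complement star offset by 2 nt (the dicer-like overhang)
hairpin_core <- function(mature, arm, loop_len) {
  loop <- rand_seq(loop_len)
  L <- nchar(mature)
  if (arm == "5p") {
    star <- revcomp(substr(mature, 3L, L))
    paste0(mature, loop, star)
  } else {
    star <- revcomp(substr(mature, 1L, L - 2L))
    paste0(star, loop, mature)
  }
}

CONSERVED_FAMILIES <- c(156, 159, 160, 164, 166, 167, 168, 171, 172, 319,
                        390, 393, 396, 398, 399, 408, 482, 1507, 2118, 5139)
REF_SPECIES <- c("gma", "mtr", "ptc", "ath", "osa")

GO_POOL <- data.frame(
  term = sprintf("GO:%07d", c(3677, 3700, 4672, 5215, 8289, 16301,
                              6412, 6355, 6810, 9058, 15979, 6281,
                              5634, 5737, 5739, 9579, 16020, 5773)),
  name = c("DNA binding", "DNA-binding transcription factor activity",
           "protein kinase activity", "transporter activity",
           "lipid binding", "kinase activity",
           "translation", "regulation of transcription", "transport",
           "biosynthetic process", "photosynthesis", "DNA repair",
           "nucleus", "cytoplasm", "mitochondrion", "thylakoid",
           "membrane", "vacuole"),
  category = rep(c("MF", "BP", "CC"), each = 6L),
  stringsAsFactors = FALSE)

KEGG_POOL <- data.frame(
  term = c("ko00195", "ko00061", "ko03450", "ko04075", "ko00500",
           "ko00010", "ko00941", "ko03010"),
  name = c("Photosynthesis", "Fatty acid biosynthesis",
           "Non-homologous end-joining", "Plant hormone signal transduction",
           "Starch and sucrose metabolism", "Glycolysis / Gluconeogenesis",
           "Flavonoid biosynthesis", "Ribosome"),
  category = "KEGG", stringsAsFactors = FALSE)

ENRICHED_GO <- "GO:0006281"    # planted enriched BP term (DNA repair)
ENRICHED_KEGG <- "ko03450"     # planted enriched pathway

#' Generate the reference bundle with planted ground truth
#'
#' Builds the unigene transcriptome (with hairpin precursors embedded for
#' every planted miRNA), the mature miRNA reference (planted conserved
#' matures plus decoys; planted novel matures are absent), the contaminant
#' ncRNA reference, planted complementarity-rule-compliant target sites,
#' and GO/KEGG annotation tables in which one GO term and one KEGG pathway
#' are enriched among the target genes of trend-carrying (differentially
#' expressed by design) miRNAs. Every planted precursor is verified by
#' refolding with the bundled engine (MFE <= -18 kcal/mol, MFEI <= -0.85
#' after trimming to the hairpin extent) and redrawn if it fails.
#'
#' @param config a [simulation_config()]
#' @return a `seedmir_ref_bundle` list: `unigenes`, `mature_ref`,
#'   `contaminants` (Biostrings::DNAStringSet), `go_annotation`,
#'   `kegg_annotation` (data frames), `truth` (planted miRNA/target/term
#'   tables and the expected count matrix)
#' @export
make_references <- function(config) {
  stopifnot(inherits(config, "seedmir_sim_config"))
  set.seed(config$rng_seed)
  model <- energy_model()

  n_uni <- config$n_unigenes
  uni_len <- sample(seq(config$unigene_length[1L], config$unigene_length[2L]),
                    n_uni, replace = TRUE)
  unigenes <- vapply(uni_len, rand_seq, character(1L))
  names(unigenes) <- sprintf("Unigene%d", seq_len(n_uni))

  n_cons <- config$n_conserved_planted
  n_nov <- config$n_novel_planted
  n_planted <- n_cons + n_nov
  origin <- rep(c("conserved", "novel"), c(n_cons, n_nov))

  mirnas <- NULL
  if (n_planted > 0L) {
    fam_num <- rep_len(CONSERVED_FAMILIES, max(n_cons, 1L))
    letters_cycle <- rep_len(letters, max(n_cons, 1L))
    seen <- character(0)
    rows <- vector("list", n_planted)
    for (i in seq_len(n_planted)) {
      arm <- sample(c("5p", "3p"), 1L)
      len <- sample(c(20L, 21L, 21L, 21L, 21L, 22L, 24L), 1L)
      host <- i                       # one precursor-bearing unigene each
      repeat {
        mature <- rand_mature(len)
        if (mature %in% seen) next
        core <- hairpin_core(mature, arm, sample(8:20, 1L))
        # verify foldability and hairpin quality of the emitted core
        f <- fold(core, model)
        ext <- hairpin_extent(f$structure)
        if (is.null(ext)) next
        m_start <- if (arm == "5p") 1L else nchar(core) - len + 1L
        pr <- trim_precursor(core, f, m_start, m_start + len - 1L)
        if (is.null(pr) || pr$mfe > -18 || pr$mfei > -0.85 ||
            pr$arm != arm) next
        # planted hairpins must satisfy the discovery criteria they are
        # meant to exercise, evaluated exactly as discovery will see them:
        # embedded in the host unigene, window-scanned and trimmed (flanks
        # can reshape the optimal stem, so a core-level check is not enough)
        offset <- sample.int(uni_len[host] - nchar(core) + 1L, 1L)
        cand_uni <- unigenes[host]
        substr(cand_uni, offset, offset + nchar(core) - 1L) <- core
        mat_at <- offset + m_start - 1L
        pw <- precursor_window(cand_uni, mat_at, mat_at + len - 1L, model)
        if (is.null(pw) || pw$mfe > -18 || pw$mfei > -0.85 ||
            pw$arm != arm || pw$mature_paired < 16L ||
            pw$mature_unpaired > 4L) next
        break
      }
      seen <- c(seen, mature)
      unigenes[host] <- cand_uni
      if (origin[i] == "conserved") {
        ref_name <- sprintf("%s-miR%d%s-%s", sample(REF_SPECIES, 1L),
                            fam_num[i], letters_cycle[i], arm)
        family <- sprintf("MIR%d", fam_num[i])
      } else {
        ref_name <- NA_character_
        family <- "novel"
      }
      rows[[i]] <- data.frame(
        truth_id = sprintf("planted_%s%02d",
                           ifelse(origin[i] == "conserved", "c", "n"),
                           ifelse(origin[i] == "conserved", i, i - n_cons)),
        sequence = mature, origin = origin[i], family = family,
        ref_name = ref_name, arm = arm,
        unigene = names(unigenes)[host],
        core_start = offset, core_end = offset + nchar(core) - 1L,
        trend = config$profile_assignments[i],
        stringsAsFactors = FALSE)
    }
    mirnas <- do.call(rbind, rows)
  } else {
    mirnas <- data.frame(truth_id = character(0), sequence = character(0),
                         origin = character(0), family = character(0),
                         ref_name = character(0), arm = character(0),
                         unigene = character(0), core_start = integer(0),
                         core_end = integer(0), trend = character(0),
                         stringsAsFactors = FALSE)
  }

  # mature reference: planted conserved + decoys (novels stay absent)
  decoys <- character(config$n_decoy_reference)
  dec_names <- character(config$n_decoy_reference)
  for (d in seq_len(config$n_decoy_reference)) {
    repeat {
      s <- rand_mature(21L)
      if (!(s %in% mirnas$sequence) && !(s %in% decoys)) break
    }
    decoys[d] <- s
    dec_names[d] <- sprintf("%s-miR%d%s-%s", sample(REF_SPECIES, 1L),
                            sample(c(1510, 1511, 2089, 2643, 4403, 530,
                                     5559, 8155, 9662), 1L),
                            sample(letters, 1L), sample(c("5p", "3p"), 1L))
  }
  cons <- mirnas[mirnas$origin == "conserved", , drop = FALSE]
  mature_ref <- c(setNames(cons$sequence, cons$ref_name),
                  setNames(decoys, dec_names))
  mature_ref <- mature_ref[!duplicated(names(mature_ref))]

  # contaminant ncRNA reference
  classes <- rep_len(c("rRNA", "tRNA", "snRNA", "snoRNA"),
                     config$n_contaminant_species)
  clens <- c(rRNA = 1600L, tRNA = 76L, snRNA = 160L, snoRNA = 110L)
  contam <- vapply(classes, function(cl) rand_seq(clens[[cl]]), character(1L))
  names(contam) <- sprintf("%s_%d class=%s", classes,
                           stats::ave(seq_along(classes), classes,
                                      FUN = seq_along), classes)

  # planted target sites in non-precursor unigenes
  host_pool <- setdiff(seq_len(n_uni), seq_len(n_planted))
  used <- vector("list", n_uni)
  trows <- list()
  for (i in seq_len(nrow(mirnas))) {
    L <- nchar(mirnas$sequence[i])
    for (h in sample(host_pool, sample(1:3, 1L))) {
      site <- revcomp(mirnas$sequence[i])
      score <- 0
      if (runif(1) < 0.5) {   # introduce a single designed G:U wobble
        m <- strsplit(mirnas$sequence[i], "")[[1L]]
        elig <- which(m %in% c("G", "T"))
        if (length(elig)) {
          k <- sample(elig, 1L)
          tp <- L + 1L - k
          substr(site, tp, tp) <- ifelse(m[k] == "G", "T", "G")
          score <- 0.5
        }
      }
      placed <- FALSE
      for (try in 1:20) {
        st <- sample.int(uni_len[h] - L + 1L, 1L)
        iv <- st:(st + L - 1L)
        if (!length(intersect(iv, unlist(used[[h]])))) {
          used[[h]] <- c(used[[h]], list(iv))
          substr(unigenes[h], st, st + L - 1L) <- site
          trows[[length(trows) + 1L]] <- data.frame(
            truth_id = mirnas$truth_id[i], unigene = names(unigenes)[h],
            start = st, end = st + L - 1L, designed_score = score,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) next
    }
  }
  targets <- if (length(trows)) do.call(rbind, trows) else
    data.frame(truth_id = character(0), unigene = character(0),
               start = integer(0), end = integer(0),
               designed_score = numeric(0), stringsAsFactors = FALSE)

  # annotations: random terms everywhere, plus the enriched term/pathway on
  # the target genes of trend-carrying (DE-by-design) miRNAs
  de_ids <- mirnas$truth_id[!(mirnas$trend %in% "flat")]
  de_hosts <- unique(targets$unigene[targets$truth_id %in% de_ids])
  go_rows <- list()
  kegg_rows <- list()
  pool_go <- GO_POOL[GO_POOL$term != ENRICHED_GO, ]
  pool_kegg <- KEGG_POOL[KEGG_POOL$term != ENRICHED_KEGG, ]
  for (g in names(unigenes)) {
    picks <- pool_go[sample.int(nrow(pool_go), sample(1:4, 1L)), ]
    go_rows[[g]] <- data.frame(gene = g, picks, stringsAsFactors = FALSE)
    if (runif(1) < 0.6) {
      kp <- pool_kegg[sample.int(nrow(pool_kegg), 1L), ]
      kegg_rows[[g]] <- data.frame(gene = g, kp, stringsAsFactors = FALSE)
    }
  }
  extra <- sample(setdiff(names(unigenes), de_hosts),
                  max(2L, round(0.02 * n_uni)))
  for (g in c(de_hosts, extra)) {
    go_rows[[paste0(g, "_enr")]] <- data.frame(
      gene = g, GO_POOL[GO_POOL$term == ENRICHED_GO, ],
      stringsAsFactors = FALSE)
    kegg_rows[[paste0(g, "_enr")]] <- data.frame(
      gene = g, KEGG_POOL[KEGG_POOL$term == ENRICHED_KEGG, ],
      stringsAsFactors = FALSE)
  }
  go_annotation <- do.call(rbind, c(go_rows, list(make.row.names = FALSE)))
  kegg_annotation <- do.call(rbind, c(kegg_rows, list(make.row.names = FALSE)))
  go_annotation <- go_annotation[order(go_annotation$gene,
                                       go_annotation$term), ]
  kegg_annotation <- kegg_annotation[order(kegg_annotation$gene,
                                           kegg_annotation$term), ]
  rownames(go_annotation) <- rownames(kegg_annotation) <- NULL

  # expected clean read counts per planted miRNA and library
  base <- round(exp(runif(n_planted, log(config$base_abundance[1L]),
                          log(config$base_abundance[2L]))))
  depth_scale <- config$phase_depths / 1e5
  expected <- matrix(0, nrow = n_planted, ncol = 9L,
                     dimnames = list(mirnas$truth_id, library_ids()))
  phase_idx <- as.integer(phase_of(library_ids()))
  for (i in seq_len(n_planted)) {
    mult <- trend_multipliers(mirnas$trend[i])
    expected[i, ] <- base[i] * mult[phase_idx] * depth_scale
  }

  structure(list(
    unigenes = Biostrings::DNAStringSet(unigenes),
    mature_ref = Biostrings::DNAStringSet(mature_ref),
    contaminants = Biostrings::DNAStringSet(contam),
    go_annotation = go_annotation,
    kegg_annotation = kegg_annotation,
    truth = list(mirnas = mirnas, targets = targets, expected = expected,
                 enriched_go = ENRICHED_GO, enriched_kegg = ENRICHED_KEGG)),
    class = "seedmir_ref_bundle")
}

# background insert length distribution: 24-nt dominant; secondary length
# 21 nt in phase I and 22 nt in the later phases (as seen in seed libraries)
background_length_probs <- function(phase) {
  lens <- 18:30
  p <- rep(0.02, length(lens))
  names(p) <- lens
  p["24"] <- 0.40
  p[as.character(if (phase == "I") 21 else 22)] <- 0.20
  p["23"] <- 0.06; p["25"] <- 0.06
  p / sum(p)
}

draw_substrings <- function(pool, n, lens) {
  idx <- sample.int(length(pool), n, replace = TRUE)
  out <- character(n)
  for (k in seq_len(n)) {
    s <- pool[idx[k]]
    L <- min(lens[k], nchar(s))
    st <- sample.int(nchar(s) - L + 1L, 1L)
    out[k] <- substr(s, st, st + L - 1L)
  }
  out
}

#' Simulate the nine small-RNA FASTQ libraries
#'
#' Emits reads for planted miRNAs (expected counts modulated by lognormal
#' replicate noise, then Poisson-sampled), contaminant ncRNA fragments,
#' degradation-like background (random unigene substrings) and the four
#' artifact classes (no 3' adapter, polyA, low quality, <18 nt). Clean
#' reads carry the 3' adapter and constant Q38 qualities (Phred+33);
#' low-quality reads have at least half their bases below Q20.
#'
#' @param bundle a `seedmir_ref_bundle` from [make_references()]
#' @param config the same [simulation_config()]
#' @param out_dir directory for the FASTQ files (created if needed)
#' @return list with `fastq` (named paths), `truth_counts` (planted miRNA x
#'   library emitted clean read counts) and `manifest` (per-library class
#'   composition; classes sum to the emitted read count)
#' @export
simulate_libraries <- function(bundle, config, out_dir) {
  stopifnot(inherits(bundle, "seedmir_ref_bundle"),
            inherits(config, "seedmir_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed + 1001L)
  libs <- library_ids()
  phases <- as.character(phase_of(libs))
  mir <- bundle$truth$mirnas
  expected <- bundle$truth$expected
  unis <- as.character(bundle$unigenes)
  contam <- as.character(bundle$contaminants)
  a3 <- config$adapter3
  truth_counts <- matrix(0L, nrow = nrow(mir), ncol = 9L,
                         dimnames = list(mir$truth_id, libs))
  manifest <- list()
  fastq <- character(0)
  for (li in seq_along(libs)) {
    lib <- libs[li]; phase <- phases[li]
    depth <- config$phase_depths[[lib]]
    n_art <- round(config$artifact_rates * depth)
    n_clean <- depth - sum(n_art)
    n_cont <- round(config$contaminant_fraction[[phase]] * n_clean)
    planted_counts <- if (nrow(mir)) {
      mu <- expected[, lib] * rlnorm(nrow(mir), -config$replicate_sigma^2 / 2,
                                     config$replicate_sigma)
      rpois(nrow(mir), mu)
    } else integer(0)
    n_planted <- sum(planted_counts)
    if (n_planted + n_cont > n_clean)
      stop("library ", lib, ": planted + contaminant reads exceed depth")
    n_bg <- n_clean - n_cont - n_planted
    truth_counts[, li] <- planted_counts

    lp <- background_length_probs(phase)
    bg <- draw_substrings(unis, n_bg,
                          sample(18:30, n_bg, replace = TRUE, prob = lp))
    # degradation background must not coincide with a planted mature, or it
    # would silently shift the planted truth counts
    while (any(hit <- bg %in% mir$sequence)) {
      bg[hit] <- draw_substrings(unis, sum(hit),
                                 sample(18:30, sum(hit), replace = TRUE,
                                        prob = lp))
    }
    inserts <- c(
      rep(mir$sequence, planted_counts),
      draw_substrings(contam, n_cont,
                      sample(18:30, n_cont, replace = TRUE, prob = lp)),
      bg)
    reads <- paste0(inserts, a3)
    quals <- strrep("G", nchar(reads))
    cls <- rep(c("planted", "contaminant", "background"),
               c(n_planted, n_cont, n_bg))

    # artifact reads
    if (n_art[["no_adapter3"]] > 0) {
      x <- draw_substrings(unis, n_art[["no_adapter3"]],
                           sample(20:28, n_art[["no_adapter3"]], TRUE))
      reads <- c(reads, x); quals <- c(quals, strrep("G", nchar(x)))
      cls <- c(cls, rep("artifact_no_adapter3", length(x)))
    }
    if (n_art[["polyA"]] > 0) {
      x <- paste0(strrep("A", sample(20:26, n_art[["polyA"]], TRUE)), a3)
      reads <- c(reads, x); quals <- c(quals, strrep("G", nchar(x)))
      cls <- c(cls, rep("artifact_polyA", length(x)))
    }
    if (n_art[["low_quality"]] > 0) {
      x <- paste0(draw_substrings(unis, n_art[["low_quality"]],
                                  sample(20:28, n_art[["low_quality"]], TRUE)),
                  a3)
      nb <- nchar(x)
      q <- vapply(nb, function(w) {
        bad <- ceiling(0.6 * w)
        paste(sample(c(rep("+", bad), rep("G", w - bad))), collapse = "")
      }, character(1L))
      reads <- c(reads, x); quals <- c(quals, q)
      cls <- c(cls, rep("artifact_low_quality", length(x)))
    }
    if (n_art[["too_short"]] > 0) {
      x <- paste0(vapply(sample(10:17, n_art[["too_short"]], TRUE), rand_seq,
                         character(1L)), a3)
      reads <- c(reads, x); quals <- c(quals, strrep("G", nchar(x)))
      cls <- c(cls, rep("artifact_too_short", length(x)))
    }

    ord <- sample.int(length(reads))
    reads <- reads[ord]; quals <- quals[ord]
    dss <- Biostrings::DNAStringSet(reads)
    names(dss) <- sprintf("%s_read%d", lib, seq_along(reads))
    path <- file.path(out_dir, paste0(lib, ".fastq"))
    suppressWarnings(
      Biostrings::writeXStringSet(dss, path, format = "fastq",
                                  qualities = Biostrings::BStringSet(quals)))
    fastq[lib] <- path
    comp <- c(table(factor(cls, levels = c(
      "planted", "contaminant", "background", "artifact_no_adapter3",
      "artifact_polyA", "artifact_low_quality", "artifact_too_short"))))
    manifest[[lib]] <- data.frame(library = lib, phase = phase,
                                  emitted = length(reads), t(comp),
                                  stringsAsFactors = FALSE)
  }
  list(fastq = fastq, truth_counts = truth_counts,
       manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))))
}

#' Write a reference bundle and simulate libraries into a directory
#'
#' Convenience wrapper producing the on-disk input layout the pipeline
#' reads: `unigenes.fa`, `mature_ref.fa`, `contaminants.fa`,
#' `go_annotation.tsv`, `kegg_annotation.tsv`, truth tables, and one FASTQ
#' per library under `reads/`.
#'
#' @param config a [simulation_config()]
#' @param dir output directory
#' @return list with all paths, the bundle and the simulation truth
#' @export
synthesize_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- make_references(config)
  paths <- list(
    unigenes = file.path(dir, "unigenes.fa"),
    mature_ref = file.path(dir, "mature_ref.fa"),
    contaminants = file.path(dir, "contaminants.fa"),
    go_annotation = file.path(dir, "go_annotation.tsv"),
    kegg_annotation = file.path(dir, "kegg_annotation.tsv"))
  Biostrings::writeXStringSet(bundle$unigenes, paths$unigenes)
  Biostrings::writeXStringSet(bundle$mature_ref, paths$mature_ref)
  Biostrings::writeXStringSet(bundle$contaminants, paths$contaminants)
  write_tsv(bundle$go_annotation, paths$go_annotation)
  write_tsv(bundle$kegg_annotation, paths$kegg_annotation)
  write_tsv(bundle$truth$mirnas, file.path(dir, "truth_mirnas.tsv"))
  write_tsv(bundle$truth$targets, file.path(dir, "truth_targets.tsv"))
  sim <- simulate_libraries(bundle, config, file.path(dir, "reads"))
  write_tsv(data.frame(truth_id = rownames(sim$truth_counts),
                       sim$truth_counts, check.names = FALSE),
            file.path(dir, "truth_counts.tsv"))
  write_tsv(sim$manifest, file.path(dir, "manifest.tsv"))
  c(paths, list(fastq = sim$fastq, bundle = bundle,
                truth_counts = sim$truth_counts, manifest = sim$manifest))
}
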