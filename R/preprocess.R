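# Raw-read filtering, adapter trimming, tag collapsing and library
# statistics. Filtering rules are explicit, deterministic replacements for
# the customary in-house scripts: each removal class is counted so that
# removal-class counts + clean reads = raw reads, exactly.

#' Filter and trim one library of raw small-RNA reads
#'
#' Applies, in order: (1) quality filter (removed if more than
#' `max_lowq_frac` of bases are below Phred `min_q`); (2) 5' adapter
#' contamination (removed if the last `adapter_k` bases of `adapter5` occur
#' within the first 10 positions); (3) 3' adapter location (exact match of
#' the first `adapter_k` bases of `adapter3` anywhere; reads without one
#' are removed, others are trimmed at the match start); (4) polyA (removed
#' if >= 80% of the trimmed insert is A, or it ends in >= 10 consecutive
#' A); (5) length bounds (trimmed inserts shorter than `min_len` or longer
#' than `max_len` are removed and counted separately).
#'
#' @param fastq path to a FASTQ file (Phred+33), or a character vector of
#'   reads accompanied by `quals`
#' @param adapter3,adapter5 adapter sequences (at least `adapter_k` nt)
#' @param quals base-quality strings when `fastq` is a sequence vector
#' @param min_len,max_len clean insert length bounds (nt)
#' @param adapter_k adapter seed length used for exact matching
#' @param min_q,max_lowq_frac quality rule parameters
#' @return list with `clean` (trimmed insert sequences) and `stats`
#'   (one-row data frame: raw, removal classes, clean, retention,
#'   n_unique_tags)
#' @export
filter_and_trim <- function(fastq, adapter3, adapter5, quals = NULL,
                            min_len = 18L, max_len = 30L, adapter_k = 8L,
                            min_q = 20L, max_lowq_frac = 0.2) {
  if (is.null(quals)) {
    rec <- read_fastq(fastq)
    reads <- rec$reads; quals <- rec$quals
  } else {
    reads <- norm_seq(fastq)
  }
  stopifnot(length(reads) == length(quals),
            nchar(adapter3) >= adapter_k, nchar(adapter5) >= adapter_k)
  n_raw <- length(reads)
  state <- rep("clean", n_raw)

  # (1) quality: count bases strictly below min_q (Phred+33)
  lowq_class <- sprintf("[\\x21-\\x%x]", 33L + as.integer(min_q) - 1L)
  n_lowq <- stringi::stri_count_regex(quals, lowq_class)
  state[n_lowq / nchar(reads) > max_lowq_frac] <- "low_quality"

  # (2) 5' adapter near the read start
  a5 <- substr(norm_seq(adapter5), nchar(adapter5) - adapter_k + 1L,
               nchar(adapter5))
  head_region <- substr(reads, 1L, 10L + adapter_k - 1L)
  hit5 <- stringi::stri_locate_first_fixed(head_region, a5)[, 1L]
  state[state == "clean" & !is.na(hit5) & hit5 <= 10L] <- "adapter5"

  # (3) 3' adapter: trim at the first exact seed match
  a3 <- substr(norm_seq(adapter3), 1L, adapter_k)
  pos3 <- stringi::stri_locate_first_fixed(reads, a3)[, 1L]
  state[state == "clean" & is.na(pos3)] <- "no_adapter3"
  insert <- substr(reads, 1L, ifelse(is.na(pos3), 0L, pos3 - 1L))

  # (4) polyA on the trimmed insert
  ok <- state == "clean"
  nA <- stringi::stri_count_fixed(insert, "A")
  ilen <- nchar(insert)
  polya <- ok & ilen > 0L &
    (nA / ilen >= 0.8 | stringi::stri_detect_regex(insert, "A{10}$"))
  state[polya] <- "polyA"

  # (5) length bounds
  state[state == "clean" & ilen < min_len] <- "too_short"
  state[state == "clean" & ilen > max_len] <- "too_long"

  clean <- insert[state == "clean"]
  classes <- c("low_quality", "adapter5", "no_adapter3", "polyA",
               "too_short", "too_long")
  removed <- vapply(classes, function(cl) sum(state == cl), integer(1L))
  stats <- data.frame(n_raw = n_raw, t(removed), n_clean = length(clean),
                      retention = if (n_raw > 0) length(clean) / n_raw else NA,
                      n_unique_tags = length(unique(clean)))
  list(clean = clean, stats = stats)
}

read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  bad <- function(i) stop("malformed FASTQ '", path, "' at record ",
                          ceiling(i / 4), call. = FALSE)
  if (n %% 4 != 0) bad(n)
  heads <- seq(1L, n, by = 4L)
  if (!all(startsWith(lines[heads], "@"))) bad(heads[!startsWith(lines[heads], "@")][1L])
  if (!all(startsWith(lines[heads + 2L], "+"))) bad(heads[!startsWith(lines[heads + 2L], "+")][1L])
  if (!all(nchar(lines[heads + 1L]) == nchar(lines[heads + 3L])))
    bad(heads[nchar(lines[heads + 1L]) != nchar(lines[heads + 3L])][1L])
  q <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  suppressWarnings(list(reads = as.character(q),
                        quals = as.character(Biostrings::quality(q))))
}

#' Collapse filtered reads into unique tags with per-library counts
#'
#' @param clean_reads named list of character vectors (one per library) of
#'   trimmed clean reads
#' @return data frame: `sequence`, `length`, one count column per library,
#'   `total`; rows sorted by sequence for determinism
#' @export
collapse_tags <- function(clean_reads) {
  stopifnot(is.list(clean_reads), !is.null(names(clean_reads)))
  tags <- sort(unique(unlist(clean_reads, use.names = FALSE)))
  counts <- vapply(clean_reads, function(x)
    tabulate(match(x, tags), nbins = length(tags)), integer(length(tags)))
  if (length(tags) == 0L)
    counts <- matrix(0L, 0L, length(clean_reads),
                     dimnames = list(NULL, names(clean_reads)))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = length(tags),
                     dimnames = list(NULL, names(clean_reads)))
  df <- data.frame(sequence = tags, length = nchar(tags), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df$total <- if (length(tags)) rowSums(df[names(clean_reads)]) else integer(0)
  df
}

#' Read-length distribution per library and per phase
#'
#' @param tags a tag table from [collapse_tags()]
#' @param min_len,max_len histogram support (nt)
#' @return list with `per_library` (length x library read counts),
#'   `per_phase`, and `modal_length` per library
#' @export
length_distribution <- function(tags, min_len = 18L, max_len = 30L) {
  libs <- setdiff(colnames(tags), c("sequence", "length", "total"))
  lens <- min_len:max_len
  per_lib <- vapply(libs, function(l)
    vapply(lens, function(L) sum(tags[[l]][tags$length == L]), numeric(1L)),
    numeric(length(lens)))
  per_lib <- matrix(per_lib, nrow = length(lens),
                    dimnames = list(lens, libs))
  ph <- phase_of(libs)
  per_phase <- vapply(levels(ph), function(p)
    rowSums(per_lib[, ph == p, drop = FALSE]), numeric(length(lens)))
  modal <- if (nrow(tags)) lens[apply(per_lib, 2L, which.max)] else integer(0)
  list(per_library = per_lib, per_phase = per_phase,
       modal_length = setNames(modal, libs))
}

#' Preprocess a set of libraries into a tag table and Table-1-style stats
#'
#' @param fastq named character vector of FASTQ paths (names = library ids)
#' @param adapter3,adapter5 adapters passed to [filter_and_trim()]
#' @param ... further arguments to [filter_and_trim()]
#' @return list with `tags` (collapsed tag table), `stats` (per-library
#'   statistics) and `clean_totals` (clean reads per library, the TPM
#'   denominator)
#' @export
preprocess_libraries <- function(fastq, adapter3, adapter5, ...) {
  stopifnot(!is.null(names(fastq)))
  res <- lapply(fastq, filter_and_trim, adapter3 = adapter3,
                adapter5 = adapter5, ...)
  stats <- do.call(rbind, c(lapply(res, `[[`, "stats"),
                            list(make.row.names = FALSE)))
  stats <- cbind(library = names(fastq), stats)
  tags <- collapse_tags(lapply(res, `[[`, "clean"))
  list(tags = tags, stats = stats,
       clean_totals = setNames(stats$n_clean, stats$library))
}
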