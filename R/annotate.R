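# Contaminant ncRNA screening: tags matching rRNA/tRNA/snRNA/snoRNA
# reference records are classified and excluded from miRNA identification.
# Matching is an ungapped full-length substring match of the tag within a
# contaminant record, up to one mismatch, on either strand - a
# deterministic desk-scale stand-in for database screening.

NC_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

#' Classify tags against a contaminant ncRNA reference
#'
#' A tag is assigned a contaminant class iff it occurs (full length,
#' ungapped, up to `max_mismatch` mismatches, either strand) inside a
#' reference record of that class. Multi-class hits are resolved by the
#' fixed priority rRNA > tRNA > snRNA > snoRNA.
#'
#' @param tags tag table from [collapse_tags()]
#' @param contaminants `DNAStringSet` (or named character vector) whose
#'   names carry a `class=` key, e.g. `rRNA_1 class=rRNA`
#' @param max_mismatch allowed mismatches (default 1)
#' @return list with `classification` (tag table plus `class` column,
#'   `unannotated` when nothing matches) and `fractions` (per-library read
#'   fraction of each class; rows sum to 1)
#' @export
classify_ncrna <- function(tags, contaminants, max_mismatch = 1L) {
  if (!inherits(contaminants, "DNAStringSet"))
    contaminants <- Biostrings::DNAStringSet(norm_seq(contaminants))
  cls <- sub(".*class=([A-Za-z]+).*", "\\1", names(contaminants))
  if (any(!grepl("class=", names(contaminants))) ||
      !all(cls %in% NC_CLASSES))
    stop("every contaminant record needs a 'class=' header key with one of: ",
         paste(NC_CLASSES, collapse = ", "))
  subjects <- c(contaminants, Biostrings::reverseComplement(contaminants))
  subj_class <- c(cls, cls)
  tag_class <- rep("unannotated", nrow(tags))
  if (nrow(tags)) {
    for (w in sort(unique(tags$length))) {
      idx <- which(tags$length == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags$sequence[idx]),
                              max.mismatch = max_mismatch)
      hits <- Biostrings::vwhichPDict(pd, subjects,
                                      max.mismatch = max_mismatch)
      for (s in seq_along(hits)) {
        if (!length(hits[[s]])) next
        h <- idx[hits[[s]]]
        pri <- match(subj_class[s], NC_CLASSES)
        cur <- match(tag_class[h], NC_CLASSES, nomatch = length(NC_CLASSES) + 1L)
        tag_class[h[pri < cur]] <- subj_class[s]
      }
    }
  }
  classification <- cbind(tags, class = tag_class, stringsAsFactors = FALSE)
  libs <- setdiff(colnames(tags), c("sequence", "length", "total"))
  frac <- vapply(libs, function(l) {
    tot <- sum(tags[[l]])
    v <- vapply(c(NC_CLASSES, "unannotated"), function(cl)
      sum(tags[[l]][tag_class == cl]), numeric(1L))
    if (tot > 0) v / tot else v * NA
  }, numeric(length(NC_CLASSES) + 1L))
  fractions <- as.data.frame(t(frac))
  fractions <- cbind(library = libs, fractions, stringsAsFactors = FALSE)
  rownames(fractions) <- NULL
  list(classification = classification, fractions = fractions)
}
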