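# Internal sequence helpers. All sequences are handled in the DNA alphabet
# (T, not U) internally; FASTA/FASTQ written by the generator use T as well,
# and U on input is accepted everywhere and converted.

BASES <- c("A", "C", "G", "T")

#' Convert a sequence to the internal DNA alphabet
#' @param x character vector of sequences (U or T, any case)
#' @return upper-case sequences with U replaced by T
#' @keywords internal
norm_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# integer coding A=0 C=1 G=2 U/T=3 used by the compiled kernels
seq_to_int <- function(x) {
  v <- utf8ToInt(norm_seq(x))
  code <- integer(length(v))
  code[v == 65L] <- 0L; code[v == 67L] <- 1L
  code[v == 71L] <- 2L; code[v == 84L] <- 3L
  bad <- !(v %in% c(65L, 67L, 71L, 84L))
  if (any(bad)) {
    stop("sequence contains non-ACGU(T) character '",
         intToUtf8(v[which(bad)[1L]]), "'")
  }
  code
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(norm_seq(x))))
}

gc_percent <- function(x) {
  x <- norm_seq(x)
  100 * stringi::stri_count_charclass(x, "[GC]") / nchar(x)
}

# named sequence vector from a DNAStringSet or a (named) character vector
as_seq_vec <- function(x) {
  s <- norm_seq(as.character(x))
  names(s) <- names(x)
  s
}

#' Path to a file shipped with seedmir
#' @param file file name under the package's extdata directory; with no
#'   argument, lists the available files
#' @return a file path (or a vector of file names)
#' @export
seedmir_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "seedmir")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no extdata file '", file, "'")
  path
}

# deterministic TSV writer (fixed options so equal inputs give equal bytes)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' The nine library ids of the three-phase, three-replicate design
#' @return character vector `MpSI-1` .. `MpSIII-3`
#' @export
library_ids <- function() {
  paste0("MpS", rep(c("I", "II", "III"), each = 3), "-", rep(1:3, 3))
}

#' Map library ids to developmental phases
#' @param libs character vector of library ids like `MpSII-1`
#' @return factor of phases `I`, `II`, `III`
#' @export
phase_of <- function(libs) {
  factor(sub("^MpS(I{1,3})-.*$", "\\1", libs), levels = c("I", "II", "III"))
}
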