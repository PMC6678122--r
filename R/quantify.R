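# TPM normalization with the 0.01 floor, phase means, log2 fold changes,
# Welch testing, DEmiR calling and trend classification, plus replicate QC
# (Pearson correlations and PCA).

#' Transcripts-per-million normalization with a 0.01 floor
#'
#' TPM = count / library_total_clean * 1e6; zero counts are floored at
#' 0.01 so fold changes stay finite.
#'
#' @param count read count(s), non-negative
#' @param library_total_clean total clean reads of the library
#' @param floor value substituted for zero counts
#' @return TPM value(s)
#' @examples
#' tpm(2, 2e7)   # 0.1
#' tpm(0, 2e7)   # 0.01 (floor)
#' @export
tpm <- function(count, library_total_clean, floor = 0.01) {
  stopifnot(library_total_clean > 0)
  if (any(count < 0)) stop("negative read count")
  v <- count / library_total_clean * 1e6
  v[count == 0] <- floor
  v
}

#' TPM matrix for a miRNA record table
#'
#' @param records miRNA record table with per-library count columns
#' @param clean_totals named vector of clean reads per library (the
#'   normalization denominator)
#' @param floor floor for zero counts
#' @return numeric matrix miRNA x library of floored TPMs, with the
#'   pre-floor column sums attached as attribute `prefloor_colsums`
#'   (each equals 1e6 when `records` covers all clean tags)
#' @export
tpm_matrix <- function(records, clean_totals, floor = 0.01) {
  libs <- intersect(colnames(records), names(clean_totals))
  counts <- as.matrix(records[, libs, drop = FALSE])
  raw <- sweep(counts, 2L, clean_totals[libs], "/") * 1e6
  out <- raw
  out[counts == 0] <- floor
  rownames(out) <- records$id
  attr(out, "prefloor_colsums") <- colSums(raw)
  out
}

#' Signed log2 fold change between two expression levels
#'
#' @param mean_b,mean_a positive expression values (numerator first:
#'   `log2fc(b, a)` = log2(b/a)); antisymmetric under argument swap
#' @return signed log2 ratio
#' @export
log2fc <- function(mean_b, mean_a) {
  stopifnot(all(mean_b > 0), all(mean_a > 0))
  log2(mean_b / mean_a)
}

#' Welch two-sample test on log2 TPMs
#'
#' The declared significance test behind DEmiR calling: Welch's t on
#' log2-transformed replicate TPMs, two-sided. With zero variance in both
#' groups the P value is 1 for equal means and 0 otherwise.
#'
#' @param tpm_b,tpm_a replicate TPM vectors (at least 2 each)
#' @return two-sided P value between 0 and 1
#' @export
de_test <- function(tpm_b, tpm_a) {
  stopifnot(length(tpm_a) >= 2L, length(tpm_b) >= 2L)
  la <- log2(tpm_a); lb <- log2(tpm_b)
  if (sd(la) == 0 && sd(lb) == 0)
    return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
  t.test(lb, la)$p.value
}

#' Classify a miRNA's phase trend from its two successive comparisons
#'
#' @param fc1,fc2 signed log2 fold changes (phase II vs I, phase III vs II)
#' @param sig1,sig2 logical significance flags of the two comparisons
#' @return one of `bell` (+,-), `V` (-,+), `up-up`, `down-down`,
#'   `single-up`, `single-down`, `ns`
#' @export
classify_trend <- function(fc1, sig1, fc2, sig2) {
  mapply(function(f1, s1, f2, s2) {
    if (s1 && s2) {
      if (f1 > 0 && f2 < 0) return("bell")
      if (f1 < 0 && f2 > 0) return("V")
      if (f1 > 0 && f2 > 0) return("up-up")
      return("down-down")
    }
    if (s1) return(if (f1 > 0) "single-up" else "single-down")
    if (s2) return(if (f2 > 0) "single-up" else "single-down")
    "ns"
  }, fc1, sig1, fc2, sig2, USE.NAMES = FALSE)
}

#' Differential expression over the three developmental phases
#'
#' Phase expression is the arithmetic mean of replicate TPMs (floored per
#' library before averaging). For each successive comparison (II vs I,
#' III vs II) the signed log2 fold change and Welch P value are computed;
#' a change is significant iff |log2FC| >= log2(`fc_threshold`) and
#' P <= `p_threshold`. The DEmiR set is the union over both comparisons,
#' and each DEmiR is classified into a phase trend.
#'
#' @param tpm TPM matrix from [tpm_matrix()]
#' @param fc_threshold absolute fold-change threshold on the linear scale
#'   (default 2, i.e. |log2FC| >= 1)
#' @param p_threshold raw P value threshold (no multiple-testing
#'   correction, by design)
#' @return data frame with phase means, log2FCs, P values, significance
#'   flags, the `demir` union flag and `trend`
#' @export
de_table <- function(tpm, fc_threshold = 2, p_threshold = 0.05) {
  libs <- colnames(tpm)
  ph <- phase_of(libs)
  m <- vapply(levels(ph), function(p)
    rowMeans(tpm[, ph == p, drop = FALSE]), numeric(nrow(tpm)))
  m <- matrix(m, nrow = nrow(tpm),
              dimnames = list(rownames(tpm), levels(ph)))
  fc1 <- log2fc(m[, "II"], m[, "I"])
  fc2 <- log2fc(m[, "III"], m[, "II"])
  p1 <- vapply(seq_len(nrow(tpm)), function(i)
    de_test(tpm[i, ph == "II"], tpm[i, ph == "I"]), numeric(1L))
  p2 <- vapply(seq_len(nrow(tpm)), function(i)
    de_test(tpm[i, ph == "III"], tpm[i, ph == "II"]), numeric(1L))
  lfc <- log2(fc_threshold)
  sig1 <- abs(fc1) >= lfc & p1 <= p_threshold
  sig2 <- abs(fc2) >= lfc & p2 <= p_threshold
  data.frame(id = rownames(tpm), mean_tpm_I = m[, "I"],
             mean_tpm_II = m[, "II"], mean_tpm_III = m[, "III"],
             log2fc_II_I = fc1, p_II_I = p1, sig_II_I = sig1,
             log2fc_III_II = fc2, p_III_II = p2, sig_III_II = sig2,
             demir = sig1 | sig2,
             trend = classify_trend(fc1, sig1, fc2, sig2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Replicate quality control: Pearson correlations and PCA
#'
#' Pearson correlations between libraries on log2 TPMs, and the first two
#' principal components of the library x miRNA matrix (covariance
#' eigendecomposition, i.e. centred, unscaled).
#'
#' @param tpm TPM matrix (miRNA x library)
#' @return list with `pearson` (library x library), `mean_r_within`
#'   (average within-phase replicate correlation per phase), `pca`
#'   (library coordinates on PC1/PC2) and `var_explained`
#' @export
replicate_qc <- function(tpm) {
  stopifnot(ncol(tpm) >= 2L)
  lt <- log2(tpm)
  keep <- apply(lt, 1L, function(x) sd(x) > 0)
  r <- suppressWarnings(cor(lt))
  ph <- phase_of(colnames(tpm))
  mean_r <- vapply(levels(ph), function(p) {
    sub <- r[ph == p, ph == p, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1L))
  pc <- prcomp(t(lt[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  list(pearson = r, mean_r_within = mean_r,
       pca = pc$x[, seq_len(k), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}
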