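# Pipeline orchestration and the small reporting utilities: Table-style
# summaries, the 2^-ddCt computation and the sequencing-vs-qPCR profile
# correlation.

#' Pipeline configuration
#'
#' Input paths plus every analysis threshold, with defaults equal to the
#' study-standard values: 18-30 nt clean inserts, more than 10 anchoring
#' reads for a precursor, absolute fold change >= 2 with P <= 0.05 for DEmiRs,
#' FDR <= 0.05 for enrichment, mismatch score cap 4 and duplex MFE ratio
#' >= 75% for targets.
#'
#' @param fastq named vector of FASTQ paths (names = library ids)
#' @param adapter3,adapter5 adapter sequences used at the filtering stage
#' @param unigenes,mature_ref,contaminants paths to the FASTA references
#' @param go_annotation,kegg_annotation paths to annotation TSVs
#' @param out_dir output directory for the result TSVs and the run log
#' @param min_len,max_len clean insert length bounds
#' @param anchor_min precursor arm-anchoring read threshold (exclusive)
#' @param fc_threshold,p_threshold DEmiR thresholds
#' @param fdr_threshold enrichment threshold
#' @param target_rules from [target_rules()]
#' @param novel_criteria from [novel_criteria()]
#' @param rng_seed seed recorded in the run log (the analysis itself is
#'   deterministic)
#' @return config list of class `seedmir_pipeline_config`
#' @export
pipeline_config <- function(fastq, unigenes, mature_ref, contaminants,
                            go_annotation, kegg_annotation, out_dir,
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            min_len = 18L, max_len = 30L, anchor_min = 10,
                            fc_threshold = 2, p_threshold = 0.05,
                            fdr_threshold = 0.05,
                            target_rules = seedmir::target_rules(),
                            novel_criteria = seedmir::novel_criteria(),
                            rng_seed = 1L) {
  stopifnot(min_len > 0, max_len >= min_len, anchor_min >= 0,
            fc_threshold > 0, p_threshold > 0, fdr_threshold > 0)
  structure(as.list(environment()), class = "seedmir_pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()]
#' @param path output YAML path
#' @return the path, invisibly
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path written by [write_config()]
#' @return a `seedmir_pipeline_config`
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$fastq <- unlist(x$fastq)
  do.call(pipeline_config, x)
}

#' Run the full pipeline
#'
#' Stages run in order: preprocess (filter/trim/collapse), annotate
#' (contaminant screening), identify (conserved matching, precursor
#' recovery, novel prediction, Venn), quantify (TPM, DE, trends, QC),
#' targets, enrichment. Every stage writes its TSV outputs under
#' `config$out_dir` and the run log records inputs and parameter values.
#' The analysis is deterministic: rerunning the same configuration
#' reproduces every output byte.
#'
#' @param config a [pipeline_config()]
#' @return list with all stage results, invisibly; outputs on disk
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "seedmir_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c("seedmir pipeline run",
                 paste0("  libraries: ", paste(names(config$fastq),
                                               collapse = ", ")),
                 paste0("  thresholds: min_len=", config$min_len,
                        " max_len=", config$max_len,
                        " anchor_min=", config$anchor_min,
                        " fc=", config$fc_threshold,
                        " p=", config$p_threshold,
                        " fdr=", config$fdr_threshold,
                        " max_score=", config$target_rules$max_score,
                        " mfe_ratio=", config$target_rules$min_ratio))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  unis <- stage("inputs", {
    u <- Biostrings::readDNAStringSet(config$unigenes)
    names(u) <- sub("\\s.*$", "", names(u))
    u
  })
  mature_ref <- Biostrings::readDNAStringSet(config$mature_ref)
  names(mature_ref) <- sub("\\s.*$", "", names(mature_ref))
  contaminants <- Biostrings::readDNAStringSet(config$contaminants)
  go_ann <- read_tsv(config$go_annotation)
  kegg_ann <- read_tsv(config$kegg_annotation)

  pre <- stage("preprocess", preprocess_libraries(
    config$fastq, adapter3 = config$adapter3, adapter5 = config$adapter5,
    min_len = config$min_len, max_len = config$max_len))
  write_tsv(pre$stats, file.path(config$out_dir, "library_stats.tsv"))
  ld <- length_distribution(pre$tags, config$min_len, config$max_len)
  write_tsv(data.frame(length = rownames(ld$per_library), ld$per_library,
                       check.names = FALSE),
            file.path(config$out_dir, "length_distribution.tsv"))

  ann <- stage("annotate", classify_ncrna(pre$tags, contaminants))
  write_tsv(ann$fractions, file.path(config$out_dir, "ncrna_fractions.tsv"))
  keep <- ann$classification$class == "unannotated"
  tags_mirna <- pre$tags[keep, , drop = FALSE]

  ident <- stage("identify", {
    conserved <- match_conserved(tags_mirna, mature_ref)
    prec_cons <- recover_precursors(conserved, pre$tags, unis,
                                    anchor_min = config$anchor_min)
    nov <- predict_novel(tags_mirna, unis,
                         exclude = as.character(mature_ref),
                         criteria = config$novel_criteria,
                         known_loci = prec_cons)
    records <- rbind(conserved, nov$records)
    list(conserved = conserved, novel = nov$records,
         precursors = rbind(prec_cons, nov$precursors), records = records,
         venn = phase_presence(records))
  })
  write_tsv(ident$records[, setdiff(colnames(ident$records), "synonyms")],
            file.path(config$out_dir, "mirna_records.tsv"))
  write_tsv(ident$precursors,
            file.path(config$out_dir, "precursors.tsv"))
  write_tsv(ident$venn, file.path(config$out_dir, "venn.tsv"))
  fa <- Biostrings::DNAStringSet(setNames(ident$records$sequence,
                                          ident$records$id))
  Biostrings::writeXStringSet(fa, file.path(config$out_dir, "mirna.fa"))

  quant <- stage("quantify", {
    mat <- tpm_matrix(ident$records, pre$clean_totals)
    de <- de_table(mat, config$fc_threshold, config$p_threshold)
    qc <- if (nrow(mat) >= 3L) replicate_qc(mat) else NULL
    list(tpm = mat, de = de, qc = qc)
  })
  write_tsv(data.frame(id = rownames(quant$tpm), quant$tpm,
                       check.names = FALSE),
            file.path(config$out_dir, "expression_tpm.tsv"))
  write_tsv(quant$de, file.path(config$out_dir, "de_results.tsv"))
  if (!is.null(quant$qc)) {
    write_tsv(data.frame(library = rownames(quant$qc$pearson),
                         quant$qc$pearson, check.names = FALSE),
              file.path(config$out_dir, "qc_pearson.tsv"))
    write_tsv(data.frame(library = rownames(quant$qc$pca), quant$qc$pca,
                         check.names = FALSE),
              file.path(config$out_dir, "qc_pca.tsv"))
  }

  sites <- stage("targets", scan_targets(
    setNames(ident$records$sequence, ident$records$id), unis,
    rules = config$target_rules))
  write_tsv(sites, file.path(config$out_dir, "targets.tsv"))

  enr <- stage("enrichment", {
    demirs <- quant$de$id[quant$de$demir]
    tgenes <- unique(sites$unigene[sites$mirna_id %in% demirs])
    ann_all <- rbind(go_ann, kegg_ann)
    if (length(tgenes))
      enrich_terms(tgenes, ann_all, names(unis),
                   fdr_threshold = config$fdr_threshold)
    else  # no DEmiR targets: nothing to test
      enrich_terms(names(unis)[1], ann_all, names(unis))[0, ]
  })
  write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))

  writeLines(c(log_lines, paste0("  stages completed: preprocess, annotate,",
                                 " identify, quantify, targets, enrichment")),
             log_path)
  invisible(list(preprocess = pre, length_dist = ld, annotate = ann,
                 identify = ident, quantify = quant, targets = sites,
                 enrichment = enr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target_sample,ct_ref_sample Ct values of the target and the
#'   reference gene in the sample of interest
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the
#'   calibrator sample
#' @return relative expression `2^-((Ctt,s - Ctr,s) - (Ctt,c - Ctr,c))`
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_calibrator, ct_ref_calibrator) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_calibrator), is.finite(ct_ref_calibrator))
  2^-((ct_target_sample - ct_ref_sample) -
        (ct_target_calibrator - ct_ref_calibrator))
}

#' Correlation between sequencing and qPCR expression profiles
#'
#' Least-squares fit and Pearson correlation of paired log2 fold changes.
#'
#' @param seq_log2fc,qpcr_log2fc paired finite vectors (length >= 3)
#' @return list with `r`, `slope`, `intercept`, `p`; all NA (with a
#'   warning) when either vector has zero variance
#' @export
profile_correlation <- function(seq_log2fc, qpcr_log2fc) {
  stopifnot(length(seq_log2fc) == length(qpcr_log2fc),
            length(seq_log2fc) >= 3L,
            all(is.finite(seq_log2fc)), all(is.finite(qpcr_log2fc)))
  if (sd(seq_log2fc) == 0 || sd(qpcr_log2fc) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                p = NA_real_))
  }
  fit <- lm(qpcr_log2fc ~ seq_log2fc)
  ct <- cor.test(seq_log2fc, qpcr_log2fc)
  list(r = unname(ct$estimate), slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]), p = ct$p.value)
}
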