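test_that("TPM follows the defining formula with the 0.01 floor", {
  expect_equal(tpm(2, 2e7), 0.1)
  expect_equal(tpm(0, 2e7), 0.01)
  expect_equal(tpm(0, 12), 0.01)
  expect_equal(tpm(5e6, 5e6), 1e6)
  expect_error(tpm(-1, 10), "negative")
  expect_error(tpm(3, 0))
})

test_that("pre-floor TPM columns over all tags sum to one million", {
  sim <- test_sim()
  tags <- sim$pre$tags
  tags$id <- tags$sequence
  mat <- tpm_matrix(tags, sim$pre$clean_totals)
  s <- attr(mat, "prefloor_colsums")
  expect_equal(unname(s), rep(1e6, 9), tolerance = 1e-9)
  expect_true(all(mat >= 0.01))
})

test_that("log2 fold change is antisymmetric and exact on examples", {
  expect_equal(log2fc(4, 1), 2)
  expect_equal(log2fc(3.7, 3.7), 0)
  set.seed(51)
  a <- runif(50, 0.01, 100); b <- runif(50, 0.01, 100)
  expect_equal(log2fc(a, b), -log2fc(b, a))
})

test_that("expression confined to phase II gives mirrored fold changes", {
  # floors in phases I and III make log2FC(II/I) = -log2FC(III/II)
  counts <- data.frame(id = "x", t(setNames(c(0, 0, 0, 2, 4, 9, 0, 0, 0),
                                            library_ids())),
                       check.names = FALSE)
  mat <- tpm_matrix(counts, setNames(rep(2e7, 9), library_ids()))
  de <- de_table(mat)
  expect_gt(de$log2fc_II_I, 0)
  expect_equal(de$log2fc_II_I, -de$log2fc_III_II)
})

test_that("the Welch test on log2 TPM behaves at its edge cases", {
  expect_equal(de_test(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(de_test(c(2, 2), c(1, 1)), 0)  # zero variance, unequal
  p <- de_test(c(8, 8.1, 7.9), c(1, 1.02, 0.98))
  expect_lt(p, 0.05)
  expect_equal(de_test(c(1, 2, 3), c(4, 5, 6)),
               de_test(c(4, 5, 6), c(1, 2, 3)))
})

test_that("DEmiR calling needs both the fold and the P threshold", {
  sig <- function(fc, p) abs(fc) >= 1 & p <= 0.05
  expect_true(sig(1.07, 0.01))    # 2.1-fold change qualifies
  expect_false(sig(0.9, 0.001))   # below 2-fold
  expect_false(sig(3, 0.2))       # not significant
})

test_that("trend classes map the signed significant changes", {
  expect_equal(classify_trend(2.01, TRUE, -2.16, TRUE), "bell")
  expect_equal(classify_trend(-2.50, TRUE, 1.13, TRUE), "V")
  expect_equal(classify_trend(1.58, TRUE, 1.49, TRUE), "up-up")
  expect_equal(classify_trend(-1.39, TRUE, -1.19, TRUE), "down-down")
  expect_equal(classify_trend(2, TRUE, -1, FALSE), "single-up")
  expect_equal(classify_trend(0.2, FALSE, -1.7, TRUE), "single-down")
  expect_equal(classify_trend(0.2, FALSE, -0.7, FALSE), "ns")
})

test_that("trend classes partition the DEmiR set", {
  sim <- test_sim()
  cons <- match_conserved(sim$tags_mirna, sim$bundle$mature_ref)
  mat <- tpm_matrix(cons, sim$pre$clean_totals)
  de <- de_table(mat)
  expect_equal(sum(de$demir), sum(de$trend != "ns"))
  both <- sum(de$sig_II_I & de$sig_III_II)
  expect_equal(sum(de$trend %in% c("bell", "V", "up-up", "down-down")), both)
})

test_that("planted trends are recovered from the simulated counts", {
  sim <- test_sim()
  cons <- match_conserved(sim$tags_mirna, sim$bundle$mature_ref)
  truth <- sim$bundle$truth$mirnas
  mat <- tpm_matrix(cons, sim$pre$clean_totals)
  de <- de_table(mat)
  de$designed <- truth$trend[match(
    cons$sequence[match(de$id, cons$id)], truth$sequence)]
  map <- c(bell = "bell", V = "V", up = "up-up", down = "down-down")
  idx <- de$designed %in% names(map)
  expect_gte(mean(de$trend[idx] == map[de$designed[idx]]), 0.9)
  # flat profiles never show a coherent two-comparison trajectory (a single
  # spurious call can slip through the raw-P threshold at low counts)
  expect_false(any(de$trend[de$designed == "flat"] %in%
                     c("bell", "V", "up-up", "down-down")))
})

test_that("replicate QC separates phases", {
  sim <- test_sim()
  cons <- match_conserved(sim$tags_mirna, sim$bundle$mature_ref)
  mat <- tpm_matrix(cons, sim$pre$clean_totals)
  qc <- replicate_qc(mat)
  # a duplicated library correlates perfectly with itself
  expect_equal(unname(diag(qc$pearson)), rep(1, 9))
  ph <- phase_of(colnames(mat))
  within <- qc$pearson[outer(ph, ph, "==") & upper.tri(qc$pearson)]
  between <- qc$pearson[outer(ph, ph, "!=") & upper.tri(qc$pearson)]
  expect_gt(mean(within), mean(between))
  # silhouette of the phase grouping on PC1/PC2 is positive
  d <- as.matrix(dist(qc$pca))
  sil <- vapply(seq_len(9), function(i) {
    a <- mean(d[i, ph == ph[i] & seq_len(9) != i])
    b <- min(vapply(setdiff(levels(ph), ph[i]),
                    function(p) mean(d[i, ph == p]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})
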