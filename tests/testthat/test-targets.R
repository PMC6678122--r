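revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# flip the target base at miRNA position k to create a full mismatch
set_mismatch <- function(site, mirna, k) {
  L <- nchar(mirna)
  tp <- L + 1 - k
  mb <- substr(mirna, k, k)
  # pick a target base that neither WC-pairs nor wobbles with mb
  bad <- switch(mb, A = "A", C = "C", G = "A", T = "T")
  substr(site, tp, tp) <- bad
  site
}

set_wobble <- function(site, mirna, k) {
  L <- nchar(mirna)
  tp <- L + 1 - k
  mb <- substr(mirna, k, k)
  stopifnot(mb %in% c("G", "T"))
  substr(site, tp, tp) <- ifelse(mb == "G", "T", "G")
  site
}

test_that("site scoring applies the five positional rules", {
  set.seed(61)
  mirna <- "GTGAGCTAGGCATTGACCTGA"  # 21 nt with G at positions 5 and 10
  perfect <- revcomp_chr(mirna)
  s0 <- score_site(mirna, perfect)
  expect_equal(s0$score, 0)
  expect_true(s0$pass)
  expect_equal(s0$mfe_ratio, 100)

  # single G:U at position 5 -> half penalty, still passing
  s1 <- score_site(mirna, set_wobble(perfect, mirna, 5))
  expect_equal(s1$score, 0.5)
  expect_true(s1$pass)
  expect_equal(unname(s1$states[5]), "GU")

  # a mismatch at position 10 violates the 10-11 rule
  s2 <- score_site(mirna, set_mismatch(perfect, mirna, 10))
  expect_false(s2$pass)
  expect_true("pos_10_11" %in% s2$failed)

  # adjacent mismatches at positions 4 and 5 violate the seed-adjacency rule
  s3 <- score_site(mirna,
                   set_mismatch(set_mismatch(perfect, mirna, 4), mirna, 5))
  expect_false(s3$pass)
  expect_true("adjacent_2_12" %in% s3$failed)

  # five scattered mismatches exceed the score cap
  s4 <- perfect
  for (k in c(1, 13, 15, 18, 21)) s4 <- set_mismatch(s4, mirna, k)
  sc4 <- score_site(mirna, s4)
  expect_equal(sc4$score, 5)
  expect_false(sc4$pass)

  # G:U at position 10 passes by default but fails when disallowed
  s5 <- set_wobble(perfect, mirna, 10)
  expect_true(score_site(mirna, s5)$pass)
  expect_false(score_site(mirna, s5,
                          target_rules(gu_ok_1011 = FALSE))$pass)

  expect_error(score_site(mirna, substr(perfect, 1, 20)), "length")
})

test_that("duplex energies sum the shipped stacking table", {
  model <- energy_model()
  mirna <- "GGCAGCAGCA"
  d <- duplex_mfe(mirna, revcomp_chr(mirna), model)
  # hand sum: pairs GC GC CG AU GC CG AU GC CG AU along the miRNA
  pairs <- c("GC", "GC", "CG", "AU", "GC", "CG", "AU", "GC", "CG", "AU")
  hand <- model$duplex_init +
    sum(vapply(seq_len(9), function(k)
      model$stack[pairs[k], pairs[k + 1]], numeric(1)))
  expect_equal(d$duplex_mfe, hand)
  expect_equal(d$perfect_mfe, hand)
  # mismatches interrupt stacking and can only weaken the duplex
  site <- set_mismatch(revcomp_chr(mirna), mirna, 5)
  d2 <- duplex_mfe(mirna, site, model)
  expect_gt(d2$duplex_mfe, d$duplex_mfe)
})

test_that("wobbles never strengthen a duplex beyond its perfect complement", {
  model <- energy_model()
  S <- model$stack
  for (q in colnames(S)) {
    expect_gte(S["GU", q], S["GC", q])
    expect_gte(S["UG", q], S["UA", q])
    expect_gte(S[q, "GU"], S[q, "GC"])
    expect_gte(S[q, "UG"], S[q, "UA"])
  }
  set.seed(62)
  for (rep in 1:25) {
    mirna <- random_seq(21)
    site <- revcomp_chr(mirna)
    ks <- which(strsplit(mirna, "")[[1]] %in% c("G", "T"))
    for (k in sample(ks, min(3, length(ks)))) site <- set_wobble(site, mirna, k)
    d <- duplex_mfe(mirna, site, model)
    expect_gte(d$duplex_mfe, d$perfect_mfe)
  }
})

test_that("pass verdicts are monotone under mismatch-to-match edits", {
  set.seed(63)
  for (rep in 1:30) {
    mirna <- random_seq(21)
    site <- revcomp_chr(mirna)
    mm <- sample(21, sample(1:5, 1))
    for (k in mm) site <- set_mismatch(site, mirna, k)
    if (!score_site(mirna, site)$pass) next
    # repair one mismatch -> must still pass
    k <- sample(mm, 1)
    tp <- nchar(mirna) + 1 - k
    fixed <- site
    substr(fixed, tp, tp) <- substr(revcomp_chr(mirna), tp, tp)
    expect_true(score_site(mirna, fixed)$pass)
  }
})

test_that("the compiled scanner equals the per-window scoring oracle", {
  set.seed(64)
  mirnas <- setNames(vapply(rep(21, 3), random_seq, character(1)),
                     c("m1", "m2", "m3"))
  uni <- random_seq(500)
  # plant one compliant site per miRNA
  pos <- c(40, 220, 430)
  for (i in 1:3) {
    site <- revcomp_chr(mirnas[[i]])
    substr(uni, pos[i], pos[i] + 20) <- site
  }
  sites <- scan_targets(mirnas, c(Unigene1 = uni))
  for (i in 1:3) {
    oracle <- scan_oracle(mirnas[[i]], uni)
    got <- sites[sites$mirna_id == names(mirnas)[i], ]
    expect_equal(got$start, oracle$start)
    expect_equal(got$score, oracle$score)
    expect_equal(got$duplex_mfe, oracle$duplex_mfe)
    expect_equal(got$mfe_ratio, oracle$ratio)
    expect_true(pos[i] %in% got$start)   # planted site recovered
  }
})

test_that("unrelated sequence yields no sites and co-targeting is kept", {
  mirnas <- c(mA = strrep("AT", 10) , mB = strrep("AT", 10))
  mirnas <- vapply(mirnas, function(x) substr(paste0(x, "G"), 1, 21),
                   character(1))
  uni <- c(Unigene1 = strrep("A", 300))  # cannot pair 21 nt against polyA
  expect_equal(nrow(scan_targets(mirnas, uni)), 0)
  # two miRNAs sharing a target gene both appear in the count table
  shared <- revcomp_chr(mirnas[["mA"]])
  uni2 <- c(Unigene2 = paste0(strrep("C", 50), shared, strrep("C", 50)))
  sites <- scan_targets(mirnas, uni2)
  counts <- target_gene_counts(sites)
  expect_setequal(counts$mirna_id, c("mA", "mB"))
})

test_that("planted target sites are recovered at their coordinates", {
  sim <- test_sim()
  truth <- sim$bundle$truth
  mirnas <- setNames(truth$mirnas$sequence, truth$mirnas$truth_id)
  sites <- scan_targets(mirnas, sim$bundle$unigenes)
  found <- merge(truth$targets, sites,
                 by.x = c("truth_id", "unigene", "start"),
                 by.y = c("mirna_id", "unigene", "start"))
  expect_equal(nrow(found), nrow(truth$targets))
  expect_equal(found$score, found$designed_score)
})
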