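test_that("conserved matching requires exact identity to the reference", {
  set.seed(41)
  m <- random_seq(21)
  m1 <- m; substr(m1, 4, 4) <- ifelse(substr(m1, 4, 4) == "G", "C", "G")
  tags <- collapse_tags(list(`MpSI-1` = c(rep(m, 3), rep(m1, 5))))
  ref <- c(`gma-miR156a-5p` = m)
  rec <- match_conserved(tags, ref)
  expect_equal(nrow(rec), 1)            # 1-mismatch tag is not conserved
  expect_equal(rec$sequence, m)
  expect_equal(rec$id, "mpi-miR156a-5p")
  expect_equal(rec$family, "MIR156")
  expect_equal(rec$arm, "5p")
  expect_equal(rec$`MpSI-1`, 3)
})

test_that("multi-reference ties keep file order and record synonyms", {
  m <- strrep("ACTGC", 5)
  m <- substr(m, 1, 21)
  tags <- collapse_tags(list(`MpSI-1` = m))
  ref <- c(`mtr-miR166a-3p` = m, `gma-miR166b-3p` = m)
  rec <- match_conserved(tags, ref)
  expect_equal(rec$id, "mpi-miR166a-3p")
  expect_equal(rec$synonyms, "gma-miR166b-3p")
})

test_that("unparsable reference names warn and fall back to unknown family", {
  m <- substr(strrep("GATCC", 5), 1, 21)
  tags <- collapse_tags(list(`MpSI-1` = m))
  expect_warning(rec <- match_conserved(tags, c(`weird-name` = m)),
                 "family")
  expect_equal(rec$family, "unknown")
})

test_that("AMFE and MFEI recompute exactly from MFE, length and GC", {
  sim <- test_sim()
  cons <- match_conserved(sim$tags_mirna, sim$bundle$mature_ref)
  prec <- recover_precursors(cons, sim$pre$tags, sim$bundle$unigenes)
  expect_gt(nrow(prec), 0)
  expect_equal(prec$amfe, prec$mfe / prec$length * 100, tolerance = 1e-12)
  expect_equal(prec$mfei, prec$amfe / prec$gc, tolerance = 1e-12)
  expect_true(all(prec$mfe <= 0))
  expect_true(all(prec$anchored_reads_5p > 10 | prec$anchored_reads_3p > 10))
})

test_that("precursors below the anchoring threshold are rejected", {
  sim <- test_sim()
  cons <- match_conserved(sim$tags_mirna, sim$bundle$mature_ref)
  # demand more anchoring reads than any planted miRNA has
  prec <- recover_precursors(cons, sim$pre$tags, sim$bundle$unigenes,
                             anchor_min = 1e7)
  expect_equal(nrow(prec), 0)
})

test_that("precursor summary statistics follow the defining formulas", {
  one <- data.frame(length = 149, gc = 43.78, mfe = -55.56)
  one$amfe <- one$mfe / one$length * 100
  one$mfei <- one$amfe / one$gc
  st <- precursor_stats(one)
  expect_equal(st$mean_amfe, -37.2885906040, tolerance = 1e-6)
  expect_equal(st$mean_mfei, -0.851726, tolerance = 1e-4)
  two <- data.frame(length = 100, gc = 50, mfe = -50)
  two$amfe <- -50; two$mfei <- -1
  st2 <- precursor_stats(rbind(
    two, data.frame(length = 100, gc = 50, mfe = -40, amfe = -40,
                    mfei = -0.8)))
  expect_equal(st2$mean_mfei, -0.9)
  expect_error(precursor_stats(two[0, ]), "empty")
})

test_that("planted novel miRNAs are recovered and background tags rejected", {
  sim <- test_sim()
  nov <- predict_novel(sim$tags_mirna, sim$bundle$unigenes,
                       exclude = as.character(sim$bundle$mature_ref))
  truth <- sim$bundle$truth$mirnas
  tn <- truth[truth$origin == "novel", ]
  expect_true(all(tn$sequence %in% nov$records$sequence))
  expect_equal(sort(nov$records$sequence), sort(tn$sequence)) # no FPs here
  # arms agree with the planted design
  arm <- nov$records$arm[match(tn$sequence, nov$records$sequence)]
  expect_equal(arm, tn$arm)
  # conserved and novel sets are disjoint
  cons <- match_conserved(sim$tags_mirna, sim$bundle$mature_ref)
  expect_length(intersect(cons$sequence, nov$records$sequence), 0)
  # every novel precursor satisfies the declared criteria
  expect_true(all(nov$precursors$mfe <= -18))
  expect_true(all(nov$precursors$mfei <= -0.85))
})

test_that("tags matching the mature reference are excluded from novel calls", {
  sim <- test_sim()
  nov <- predict_novel(sim$pre$tags, sim$bundle$unigenes,
                       exclude = as.character(sim$bundle$mature_ref))
  cons_seq <- intersect(sim$pre$tags$sequence,
                        seedmir:::norm_seq(as.character(sim$bundle$mature_ref)))
  expect_length(intersect(nov$records$sequence, cons_seq), 0)
})

test_that("phase presence partitions miRNAs into the designed Venn regions", {
  mk <- function(id, counts) {
    df <- data.frame(id = id, origin = "conserved",
                     stringsAsFactors = FALSE)
    for (i in seq_along(library_ids())) df[[library_ids()[i]]] <- counts[i]
    df
  }
  recs <- rbind(mk("a", c(0, 0, 0, 1, 2, 0, 0, 0, 0)),  # II only
                mk("b", c(1, 1, 1, 1, 1, 1, 1, 1, 1)),  # all three
                mk("c", c(3, 0, 0, 0, 0, 0, 0, 0, 2)))  # I and III
  v <- phase_presence(recs)
  expect_equal(v$conserved[v$region == "II only"], 1)
  expect_equal(v$conserved[v$region == "I&II&III"], 1)
  expect_equal(v$conserved[v$region == "I&III"], 1)
  expect_equal(sum(v$conserved), 3)
})

test_that("designed phase-exclusive miRNAs land in their exclusive region", {
  sim <- test_sim()
  cons <- match_conserved(sim$tags_mirna, sim$bundle$mature_ref)
  truth <- sim$bundle$truth$mirnas
  cons$truth <- truth$trend[match(cons$sequence, truth$sequence)]
  v <- phase_presence(cons)
  excl <- table(factor(sub("phase(I+)_only", "\\1 only",
                           cons$truth[grepl("only", cons$truth)]),
                       levels = c("I only", "II only", "III only")))
  for (reg in names(excl))
    expect_gte(v$conserved[v$region == reg], unname(excl[[reg]]))
  expect_equal(sum(v$conserved), nrow(cons))
})
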