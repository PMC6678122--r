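test_that("fixed seeds give byte-identical references and libraries", {
  cfg <- simulation_config(rng_seed = 9L, phase_depths = 400,
                           n_unigenes = 40L, n_conserved_planted = 3L,
                           n_novel_planted = 2L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  i1 <- synthesize_inputs(cfg, d1)
  i2 <- synthesize_inputs(cfg, d2)
  for (f in c("unigenes.fa", "mature_ref.fa", "contaminants.fa",
              "go_annotation.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  for (l in names(i1$fastq))
    expect_identical(readLines(i1$fastq[[l]]), readLines(i2$fastq[[l]]),
                     label = l)
})

test_that("planted precursors refold into qualifying single stem-loops", {
  b <- test_sim()$bundle
  truth <- b$truth$mirnas
  unis <- as.character(b$unigenes)
  for (i in seq_len(nrow(truth))) {
    core <- substr(unis[[truth$unigene[i]]], truth$core_start[i],
                   truth$core_end[i])
    f <- fold(core)
    expect_lt(f$mfe, 0)
    # mature occurs verbatim in its designated arm of the refolded core
    m_at <- regexpr(truth$sequence[i], core, fixed = TRUE)
    expect_gt(m_at, 0)
    pr <- seedmir:::trim_precursor(core, f, as.integer(m_at),
                                   as.integer(m_at) +
                                     nchar(truth$sequence[i]) - 1L)
    expect_false(is.null(pr))
    expect_equal(pr$arm, truth$arm[i])
    expect_lte(pr$mfei, -0.85)
    expect_lte(pr$mfe, -18)
  }
})

test_that("emitted read counts decompose exactly into truth classes", {
  sim <- test_sim()
  man <- sim$inp$manifest
  for (r in seq_len(nrow(man))) {
    lib <- man$library[r]
    n_lines <- length(readLines(sim$inp$fastq[[lib]]))
    expect_equal(n_lines %% 4, 0)
    expect_equal(man$emitted[r],
                 sum(man[r, c("planted", "contaminant", "background",
                              "artifact_no_adapter3", "artifact_polyA",
                              "artifact_low_quality", "artifact_too_short")]))
    expect_equal(n_lines / 4, man$emitted[r])
    expect_equal(man$planted[r], sum(sim$inp$truth_counts[, lib]))
  }
})

test_that("an empty conserved truth yields no conserved calls downstream", {
  cfg <- simulation_config(rng_seed = 5L, phase_depths = 300,
                           n_unigenes = 30L, n_conserved_planted = 0L,
                           n_novel_planted = 1L)
  d <- file.path(tempdir(), "empty-cons")
  inp <- synthesize_inputs(cfg, d)
  pre <- preprocess_libraries(inp$fastq, cfg$adapter3, cfg$adapter5)
  cons <- match_conserved(pre$tags, inp$bundle$mature_ref)
  expect_equal(nrow(cons), 0)
})

test_that("artifact-free reads are fully retained and planted matures round-trip", {
  cfg <- simulation_config(
    rng_seed = 11L, phase_depths = 600, n_unigenes = 30L,
    n_conserved_planted = 4L, n_novel_planted = 0L,
    artifact_rates = c(no_adapter3 = 0, polyA = 0, low_quality = 0,
                       too_short = 0),
    contaminant_fraction = c(I = 0, II = 0, III = 0))
  d <- file.path(tempdir(), "clean-sim")
  inp <- synthesize_inputs(cfg, d)
  pre <- preprocess_libraries(inp$fastq, cfg$adapter3, cfg$adapter5)
  # background substrings 18-30 nt and matures all survive filtering
  expect_true(all(pre$stats$retention == 1))
  cons <- match_conserved(pre$tags, inp$bundle$mature_ref)
  truth <- inp$bundle$truth$mirnas
  expect_setequal(cons$sequence, truth$sequence)
  # per-library conserved counts equal emitted truth counts exactly
  for (lib in library_ids()) {
    got <- cons[[lib]][match(truth$sequence, cons$sequence)]
    expect_equal(got, unname(inp$truth_counts[, lib]))
  }
})

test_that("bell-shaped planted profiles have elevated phase II truth counts", {
  sim <- test_sim()
  truth <- sim$bundle$truth$mirnas
  tc <- sim$inp$truth_counts
  ph <- phase_of(colnames(tc))
  bells <- truth$truth_id[truth$trend == "bell"]
  for (id in bells) {
    m <- tapply(tc[id, ], ph, mean)
    expect_gt(m[["II"]], m[["I"]])
    expect_gt(m[["II"]], m[["III"]])
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(artifact_rates = c(
    no_adapter3 = 0.5, polyA = 0.4, low_quality = 0.2, too_short = 0.1)))
  expect_error(simulation_config(n_unigenes = 10L))
  expect_error(simulation_config(phase_depths = c(1, 2)))
})
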