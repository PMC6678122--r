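# Independent oracles used across the suite. None of these share code with
# the package implementations they check.

base_int <- function(seq_chr) {
  v <- utf8ToInt(toupper(gsub("[Uu]", "T", seq_chr)))
  unname(c(A = 0L, C = 1L, G = 2L, T = 3L)[intToUtf8(v, multiple = TRUE)])
}

pair_idx <- function(a, b) {
  key <- paste0(a, b)
  m <- c("03" = 1L, "30" = 2L, "21" = 3L, "12" = 4L, "23" = 5L, "32" = 6L)
  out <- m[key]
  ifelse(is.na(out), 0L, out) # 0 = unpairable; 1..6 index into stack rows
}

# ---- folding oracle 1: exhaustive enumeration of single-stem chains ------
# Generates every chain of nested pairs explicitly and evaluates each with
# a standalone energy function; practical up to ~32 nt.
enumerate_fold_mfe <- function(seq_chr, model = energy_model()) {
  s <- base_int(seq_chr)
  n <- length(s)
  chain_energy <- function(pairs) {
    k <- nrow(pairs)
    e <- model$hairpin_a + model$hairpin_b * (pairs[k, 2] - pairs[k, 1] - 1)
    if (k > 1) for (r in 2:k) {
      g1 <- pairs[r, 1] - pairs[r - 1, 1] - 1
      g2 <- pairs[r - 1, 2] - pairs[r, 2] - 1
      e <- e + if (g1 == 0 && g2 == 0)
        model$stack[pair_idx(s[pairs[r - 1, 1]], s[pairs[r - 1, 2]]),
                    pair_idx(s[pairs[r, 1]], s[pairs[r, 2]])]
      else model$loop_a + model$loop_b * (g1 + g2)
    }
    e
  }
  best <- 0
  grow <- function(pairs) {
    e <- chain_energy(pairs)
    if (e < best) best <<- e
    p <- pairs[nrow(pairs), 1]; q <- pairs[nrow(pairs), 2]
    for (k in (p + 1):min(p + 1 + model$max_gap, q - 1))
      for (l in (q - 1):max(q - 1 - model$max_gap, k + 1)) {
        if (l - k - 1 < model$min_loop) next
        if (pair_idx(s[k], s[l]) == 0L) next
        grow(rbind(pairs, c(k, l)))
      }
  }
  for (i in seq_len(n - 1))
    for (j in seq(i + model$min_loop + 1, n)) {
      if (j > n) break
      if (pair_idx(s[i], s[j]) > 0L) grow(matrix(c(i, j), 1))
    }
  best
}

# ---- folding oracle 2: plain-R bottom-up evaluation of the model ---------
# Independent implementation of the single-stem energy model (shared model
# definition only); tractable to 60+ nt.
fold_reference_mfe <- function(seq_chr, model = energy_model()) {
  s <- base_int(seq_chr)
  n <- length(s)
  E <- matrix(Inf, n, n)
  for (span in seq(model$min_loop + 1, n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      pij <- pair_idx(s[i], s[j])
      if (pij == 0L) next
      best <- model$hairpin_a + model$hairpin_b * (j - i - 1)
      for (k in (i + 1):min(i + 1 + model$max_gap, j - 1))
        for (l in (j - 1):max(j - 1 - model$max_gap, k + 1)) {
          if (l - k - 1 < model$min_loop || !is.finite(E[k, l])) next
          step <- if (k == i + 1 && l == j - 1)
            model$stack[pij, pair_idx(s[k], s[l])]
          else model$loop_a + model$loop_b * ((k - i - 1) + (j - l - 1))
          if (E[k, l] + step < best) best <- E[k, l] + step
        }
      E[i, j] <- best
    }
  }
  min(0, suppressWarnings(min(E)))
}

# ---- target-scan oracle: per-window scoring via score_site ---------------
scan_oracle <- function(mirna, unigene, rules = target_rules(),
                        model = energy_model()) {
  L <- nchar(mirna)
  rows <- list()
  for (st in seq_len(nchar(unigene) - L + 1)) {
    w <- substr(unigene, st, st + L - 1)
    sc <- score_site(mirna, w, rules, model)
    if (sc$pass)
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, score = sc$score, duplex_mfe = sc$duplex_mfe,
        ratio = sc$mfe_ratio)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), score = numeric(0),
                      duplex_mfe = numeric(0), ratio = numeric(0)))
  do.call(rbind, rows)
}

# ---- hypergeometric oracle: closed-form enumeration over k' >= k ---------
hyper_oracle <- function(k, K, N, n) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# ---- shared small synthetic experiment (built once, lazily) --------------
.fixtures <- new.env()

test_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- simulation_config(rng_seed = 42L, phase_depths = 8000,
                             n_unigenes = 60L, n_conserved_planted = 8L,
                             n_novel_planted = 5L,
                             profile_assignments = c(
                               "bell", "V", "up", "down", "phaseI_only",
                               "phaseII_only", "phaseIII_only", "flat",
                               "bell", "V", "up", "down", "flat"))
    dir <- file.path(tempdir(), "seedmir-fixture")
    inp <- synthesize_inputs(cfg, dir)
    pre <- preprocess_libraries(inp$fastq, cfg$adapter3, cfg$adapter5)
    ann <- classify_ncrna(pre$tags, inp$bundle$contaminants)
    .fixtures$sim <- list(cfg = cfg, dir = dir, inp = inp, bundle = inp$bundle,
                          pre = pre, ann = ann,
                          tags_mirna = pre$tags[
                            ann$classification$class == "unannotated", ,
                            drop = FALSE])
  }
  .fixtures$sim
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
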