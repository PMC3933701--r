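# Conservation profiling, candidate enumeration, validation and pairing.

test_that("conservation profile covers observed bases with minimal codes", {
  aln <- recs(a = "ACGTACGTAC", b = "ACGTACGTAC")
  prof <- conservation_profile(aln)
  expect_true(all(prof$gap_fraction == 0))
  expect_identical(paste(prof$consensus, collapse = ""), "ACGTACGTAC")

  # {A, A, T} -> W; {A, A, -} -> gap fraction 1/3
  aln2 <- recs(a = "AA", b = "AA", c = "T-")
  prof2 <- conservation_profile(aln2)
  expect_identical(prof2$consensus[1], "W")
  expect_equal(prof2$gap_fraction[2], 1 / 3)
  expect_equal(prof2$n_A, c(2, 2))
  expect_equal(prof2$n_T[1], 1)

  # an ambiguity code in a row demands cover of its full expansion
  aln3 <- recs(a = "A", b = "R")
  expect_identical(conservation_profile(aln3)$consensus, "R")
  # f_min above the minor-allele frequency drops it
  aln4 <- recs(a = "A", b = "A", c = "A", d = "C")
  expect_identical(conservation_profile(aln4, f_min = 0.5)$consensus, "A")
  expect_identical(conservation_profile(aln4, f_min = 0)$consensus, "M")
})

test_that("Wallace Tm equals the brute-force expansion average", {
  expect_equal(tm_wallace("ACGT"), 12)
  expect_equal(tm_wallace("AAAA"), 8)
  for (p in c(incp9_forward, incp9_reverse, "RYSWKM", "NNNN")) {
    expect_equal(tm_wallace(p), tm_wallace_oracle(p), info = p)
  }
})

test_that("candidate validation applies the anchor and budget rules", {
  cons <- primer_constraints()
  target <- paste0(strrep("C", 20), expand_primer(incp9_forward)[1],
                   strrep("C", 20))
  rep <- validate_candidate(incp9_forward, recs(t = target), cons, "forward")
  expect_true(rep$pass)
  expect_identical(rep$n_mismatch, 0L)
  expect_identical(rep$anchor_run, 21L)

  # substitution 3 nt from the 3' end truncates the anchor to 3
  damaged <- target
  substr(damaged, 20 + 21 - 3, 20 + 21 - 3) <- "C"  # position 18 of the site
  rep2 <- validate_candidate(incp9_forward, recs(t = damaged), cons, "forward")
  expect_identical(rep2$anchor_run, 3L)
  expect_false(rep2$pass)

  # five substitutions in the 5' third blow the mismatch budget
  worse <- target
  substr(worse, 21, 25) <- strrep("C", 5)
  stopifnot(substr(target, 21, 25) != substr(worse, 21, 25))
  rep3 <- validate_candidate(incp9_forward, recs(t = worse), cons, "forward")
  expect_identical(rep3$n_mismatch, 5L)
  expect_false(rep3$pass)
  expect_identical(rep3$anchor_run, 16L)

  rep4 <- validate_candidate(incp9_forward, recs(t = "ACGT"), cons, "forward")
  expect_false(rep4$pass)
  expect_identical(rep4$reason, "too short")
})

test_that("a panel of primer expansions yields self-recovering candidates", {
  exps <- expand_primer(incp9_forward)
  flank5 <- strrep("ACGTG", 6)
  flank3 <- strrep("TGCAC", 6)
  panel <- recs(e1 = paste0(flank5, exps[1], flank3),
                e2 = paste0(flank5, exps[2], flank3))
  aln <- align_sequences(panel)
  prof <- conservation_profile(aln)
  cand <- enumerate_candidates(prof, aln, primer_constraints(), "forward")
  expect_true(incp9_forward %in% cand$sequence)
  hit <- cand[cand$sequence == incp9_forward, ]
  expect_identical(hit$window_start, 31L)
  expect_equal(hit$degeneracy, 2)

  # max_degeneracy = 1 excludes every window containing the W column
  strict <- primer_constraints(max_degeneracy = 1)
  cand1 <- suppressMessages(
    enumerate_candidates(prof, aln, strict, "forward"))
  expect_false(any(cand1$window_start <= 48 & cand1$window_end >= 48))
})

test_that("pairing enforces the amplicon window and the rank key", {
  panel <- simulate_panel(sim_config(seed = 3, seqs_per_subgroup = 2))
  des <- design_primers(panel$targets)
  expect_gt(nrow(des$pairs), 0)
  best <- des$pairs[1, ]
  # every emitted pair satisfies the window target-by-target, re-checked
  # by the independent in-silico PCR route
  for (k in seq_len(nrow(des$pairs))) {
    p <- des$pairs[k, ]
    amp <- predict_amplicons(p$fwd_sequence, p$rev_sequence, panel$targets,
                             size_window = c(610, 637))
    expect_identical(sort(unique(amp$id)), sort(panel$targets$id))
    expect_identical(
      sort(amp$length),
      sort(p$per_target[[1]]$amplicon_length))
  }
  # planted-site recovery: top pair coordinates equal the generator truth
  pt <- merge(best$per_target[[1]], panel$truth, by.x = "target_id",
              by.y = "id")
  expect_true(all(pt$fwd_start.x == pt$fwd_start.y))
  expect_true(all(pt$rev_end.x == pt$rev_end.y))
  expect_true(all(pt$amplicon_length.x == pt$amplicon_length.y))
  # rank key: degeneracy dominates
  expect_identical(best$max_degeneracy, min(des$pairs$max_degeneracy))

  # an impossible amplicon window empties the result
  none <- pair_primers(des$forward, des$reverse,
                       primer_constraints(amplicon_min = 43, amplicon_max = 44))
  expect_identical(nrow(none), 0L)
})

test_that("tightening constraints never enlarges the candidate set", {
  panel <- simulate_panel(sim_config(seed = 23, seqs_per_subgroup = 1))
  aln <- align_sequences(panel$targets)
  base <- primer_constraints(max_degeneracy = 16, max_mismatch = 6,
                             anchor_len = 8)
  prof <- conservation_profile(aln)
  loose <- suppressMessages(enumerate_candidates(prof, aln, base, "forward"))
  key <- function(x) paste(x$window_start, x$sequence)
  for (tighter in list(
    primer_constraints(max_degeneracy = 2, max_mismatch = 6, anchor_len = 8),
    primer_constraints(max_degeneracy = 16, max_mismatch = 1, anchor_len = 8),
    primer_constraints(max_degeneracy = 16, max_mismatch = 6, anchor_len = 16)
  )) {
    tight <- suppressMessages(
      enumerate_candidates(prof, aln, tighter, "forward"))
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("windows never cross gap-containing columns by default", {
  aln <- recs(a = paste0(strrep("A", 30), "-", strrep("C", 30)),
              b = paste0(strrep("A", 30), "G", strrep("C", 30)))
  prof <- conservation_profile(aln)
  cand <- suppressMessages(
    enumerate_candidates(prof, aln, primer_constraints(primer_length = 10,
                                                       anchor_len = 5,
                                                       amplicon_min = 20,
                                                       amplicon_max = 60,
                                                       tm_min = 0, tm_max = 99),
                         "forward"))
  expect_false(any(cand$window_start <= 31 & cand$window_end >= 31))
})
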