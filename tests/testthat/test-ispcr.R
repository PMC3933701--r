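# Binding-site discovery, amplicon prediction and specificity screening.

test_that("an exact planted forward site is found with full anchor", {
  set.seed(21)
  primer <- "GAGGGTTTGGAGATCATAAGA"  # a concrete expansion
  subj <- random_dna(100)
  substr(subj, 11, 31) <- primer
  sites <- find_binding_sites(incp9_forward, recs(s = subj))
  plus <- sites[sites$strand == "+", ]
  expect_identical(nrow(plus), 1L)
  expect_identical(plus$start, 11L)
  expect_identical(plus$end, 31L)
  expect_identical(plus$n_mismatch, 0L)
  expect_identical(plus$anchor_run, 21L)
  expect_length(plus$mismatch_positions[[1]], 0L)

  # strand symmetry: the mirrored site on the reverse complement
  rc_subj <- reverse_complement(subj)
  mirrored <- find_binding_sites(incp9_forward, recs(s = rc_subj))
  minus <- mirrored[mirrored$strand == "-", ]
  expect_identical(nrow(minus), 1L)
  expect_identical(minus$start, 100L - 31L + 1L)
  expect_identical(minus$end, 100L - 11L + 1L)
})

test_that("binding-site finder agrees with the naive oracle", {
  cons <- primer_constraints()
  set.seed(31)
  primers <- c(incp9_forward, incp9_reverse, "ACGTNACGTNAC", "TTTTTTTTTTTT")
  for (p in primers) {
    for (k in 1:3) {
      subj <- random_dna(300)
      # sometimes plant a (possibly damaged) site
      if (k > 1) {
        site <- expand_primer(p)[1]
        pos <- sample(250, 1)
        if (k == 3) substr(site, 2, 2) <- "A"
        substr(subj, pos, pos + nchar(p) - 1L) <- site
      }
      got <- find_binding_sites(p, recs(s = subj), cons)
      want <- naive_find_sites(p, subj, cons$anchor_len, cons$max_mismatch)
      expect_identical(nrow(got), nrow(want), info = p)
      if (nrow(got)) {
        expect_identical(got$start, want$start)
        expect_identical(got$strand, want$strand)
        expect_identical(got$n_mismatch, want$n_mismatch)
        expect_identical(got$anchor_run, want$anchor_run)
      }
    }
  }
  # record shorter than primer: empty, not an error
  expect_identical(nrow(find_binding_sites(incp9_forward, recs(tiny = "ACGT"))), 0L)
})

make_template <- function(insert_len, seed = 1) {
  set.seed(seed)
  fwd_site <- expand_primer(incp9_forward)[1]
  rev_site <- reverse_complement(expand_primer(incp9_reverse)[1])
  paste0(random_dna(30), fwd_site, random_dna(insert_len), rev_site,
         random_dna(30))
}

test_that("amplicon arithmetic matches the planted construction", {
  subj <- make_template(568)
  amp <- predict_amplicons(incp9_forward, incp9_reverse, recs(t = subj))
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$length, 610L)
  expect_identical(amp$start, 31L)
  expect_identical(amp$end, 31L + 610L - 1L)
  # extracted subsequence length equals the reported length
  seqs <- amplicon_sequences(amp, recs(t = subj))
  expect_identical(nchar(seqs$seq), amp$length)

  # boundary: insert 596 -> product 638, excluded by the 610-637 window
  subj2 <- make_template(596)
  amp2 <- predict_amplicons(incp9_forward, incp9_reverse, recs(t = subj2),
                            size_window = c(610, 637))
  expect_identical(nrow(amp2), 0L)
  expect_identical(
    predict_amplicons(incp9_forward, incp9_reverse, recs(t = subj2))$length,
    638L)
})

test_that("multiple upstream sites yield one amplicon per combination", {
  set.seed(41)
  fwd_site <- expand_primer(incp9_forward)[2]
  rev_site <- reverse_complement(expand_primer(incp9_reverse)[1])
  subj <- paste0(random_dna(10), fwd_site, random_dna(50), fwd_site,
                 random_dna(100), rev_site, random_dna(10))
  amp <- predict_amplicons(incp9_forward, incp9_reverse, recs(t = subj))
  expect_identical(nrow(amp), 2L)
  expect_identical(sort(amp$fwd_start), c(11L, 82L))
  expect_identical(length(unique(amp$rev_start)), 1L)
})

test_that("amplicon prediction is strand-consistent", {
  subj <- make_template(100, seed = 9)
  n <- nchar(subj)
  fwd_amp <- predict_amplicons(incp9_forward, incp9_reverse, recs(t = subj))
  rev_amp <- predict_amplicons(incp9_forward, incp9_reverse,
                               recs(t = reverse_complement(subj)))
  expect_identical(nrow(fwd_amp), 1L)
  expect_identical(nrow(rev_amp), 1L)
  expect_identical(rev_amp$start, n - fwd_amp$end + 1L)
  expect_identical(rev_amp$end, n - fwd_amp$start + 1L)
  expect_identical(rev_amp$length, fwd_amp$length)
  expect_identical(rev_amp$orientation, "-")
})

test_that("specificity screen separates targets from site-free decoys", {
  panel <- simulate_panel(sim_config(seed = 13, seqs_per_subgroup = 1,
                                     n_nontargets = 4))
  rep <- specificity_screen(incp9_forward, incp9_reverse,
                            panel$targets, panel$nontargets)
  g <- glance(rep)
  expect_identical(g$targets_amplified, 9L)
  expect_identical(g$nontargets_amplified, 0L)
  expect_true(fully_specific(rep))

  # a decoy carrying a planted site pair is flagged
  bad_decoy <- recs(mole = make_template(580, seed = 2))
  bad_decoy$group <- NULL
  rep2 <- specificity_screen(incp9_forward, incp9_reverse,
                             panel$targets, bad_decoy)
  expect_false(fully_specific(rep2))
  t2 <- tidy(rep2)
  expect_true(t2$amplified[t2$id == "mole"])

  # single-target panel equal to an expansion pair
  rep3 <- specificity_screen(incp9_forward, incp9_reverse,
                             recs(one = make_template(570, seed = 3)))
  expect_true(fully_specific(rep3))
  expect_error(specificity_screen(incp9_forward, incp9_reverse,
                                  recs(one = "ACGT")[0, ]), "empty panel")
})
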