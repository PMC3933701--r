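# Distances, neighbor joining, bootstrap and subgroup classification.

test_that("p-distance uses pairwise deletion and literal inequality", {
  aln <- recs(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_equal(p_distance(aln)["a", "b"], 0)

  aln2 <- recs(a = "ACGTACGTAC", b = "ACGTACGTAT")
  expect_equal(p_distance(aln2)["a", "b"], 0.1)

  aln3 <- recs(a = "AC-T", b = "ACGT")
  expect_equal(p_distance(aln3)["a", "b"], 0)

  # an ambiguity code is a literal difference, not an intersection match
  aln4 <- recs(a = "AAAW", b = "AAAA")
  expect_equal(p_distance(aln4)["a", "b"], 0.25)

  aln5 <- recs(a = "AC--", b = "--GT")
  expect_error(p_distance(aln5), "no comparable columns")
})

test_that("distances agree with ape's JC69 on gapped alignments", {
  set.seed(17)
  base <- strsplit(random_dna(80), "")[[1]]
  seqs <- vapply(1:6, function(k) {
    s <- base
    s[sample(80, 8)] <- sample(c("A", "C", "G", "T", "-"), 8, replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:6)
  aln <- recs(seqs)
  mine <- dist_matrix(aln, model = "JC")
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(seqs), ""), identity)))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("Jukes-Cantor correction matches its closed form and domain", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.1), 0.1073256, tolerance = 1e-6)
  expect_error(jc_correct(0.75), "saturated")
  expect_error(jc_correct(-0.01), "negative")
  # strictly increasing and >= p on a grid
  p <- seq(0, 0.74, by = 0.01)
  d <- jc_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("neighbor joining resolves the additive 4-taxon case exactly", {
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  # split AB|CD with internal branch 1 and pendant branches 1
  parts <- ape::prop.part(ape::unroot(tr))
  labs <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  has <- function(x) any(vapply(labs, identical, logical(1), x))
  expect_true(has(c("A", "B")) || has(c("C", "D")))
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1, 1))
  # distances re-derived from the tree reproduce the input
  expect_equal(unname(as.matrix(cophenetic(tr))[LETTERS[1:4], LETTERS[1:4]]),
               unname(d))
})

test_that("three taxa resolve by the closed three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["x"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["y"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["z"]], (4 + 5 - 3) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  dbad <- d; dbad[1, 2] <- 9
  expect_error(nj_tree(dbad), "symmetric")
})

test_that("NJ recovers random additive topologies (ape as cross-check)", {
  set.seed(99)
  for (k in 1:40) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(nb) stats::runif(nb, 0.1, 1))
    d <- cophenetic(tr)
    mine <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(mine)), 0,
                 ignore_attr = TRUE)
    ref <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(mine)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("all-equal distances join the lowest-index pair first", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- nj_tree(d)
  parts <- ape::prop.part(ape::unroot(tr))
  labs <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(any(vapply(labs, identical, logical(1), c("a", "b"))))
})

split_fixture <- function() {
  g1 <- paste0(strrep("ACGTACGTAC", 3), "AAAAACCCCC")
  g2 <- paste0(strrep("ACGTACGTAC", 3), "TTTTTGGGGG")
  recs(s1 = g1, s2 = g1, s3 = g1, s4 = g2, s5 = g2, s6 = g2)
}

test_that("bootstrap gives full support to a perfectly split alignment", {
  aln <- split_fixture()
  tr <- bootstrap_support(aln, n_reps = 100, seed = 3)
  supports <- as.integer(tr$node.label[tr$node.label != ""])
  expect_true(all(supports == 100))
  # determinism and {0, 100} supports at a single replicate
  tr2 <- bootstrap_support(aln, n_reps = 100, seed = 3)
  expect_identical(write_newick(tr), write_newick(tr2))
  tr1 <- bootstrap_support(aln, n_reps = 1, seed = 8)
  s1 <- as.integer(tr1$node.label[tr1$node.label != ""])
  expect_true(all(s1 %in% c(0L, 100L)))
  expect_error(bootstrap_support(aln, n_reps = 0), "n_reps")
})

test_that("bootstrap supports are invariant to row order", {
  # rows carry distinct private mutations so no distances tie
  set.seed(77)
  base1 <- strsplit(paste0(strrep("ACGTACGTAC", 4), "AAAAACCCCC"), "")[[1]]
  base2 <- base1
  base2[41:50] <- c("T", "T", "T", "T", "T", "G", "G", "G", "G", "G")
  mk <- function(base, k) {
    s <- base
    pos <- sample(40, 3)
    s[pos] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    paste(s, collapse = "")
  }
  seqs <- c(mk(base1), mk(base1), mk(base1), mk(base2), mk(base2), mk(base2))
  names(seqs) <- paste0("s", 1:6)
  aln <- recs(seqs)
  tr <- bootstrap_support(aln, n_reps = 60, seed = 12)
  trp <- bootstrap_support(aln[c(4, 2, 6, 1, 3, 5), ], n_reps = 60, seed = 12)
  key <- function(t) {
    all_labs <- sort(t$tip.label)
    parts <- ape::prop.part(t)
    labs <- vapply(seq_along(parts), function(i) {
      side <- sort(attr(parts, "labels")[parts[[i]]])
      # canonical unrooted split: the side containing the first label
      if (!(all_labs[1] %in% side)) side <- setdiff(all_labs, side)
      paste(side, collapse = ",")
    }, character(1))
    sort(paste(labs, t$node.label, sep = "="))
  }
  expect_identical(key(tr), key(trp))
})

test_that("classification assigns by nearest reference with tau cutoff", {
  set.seed(55)
  refA <- random_dna(120)
  refB <- strsplit(refA, "")[[1]]
  refB[sample(120, 40)] <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
  refB <- paste(refB, collapse = "")
  references <- tibble::tibble(
    id = c("rA", "rB"), description = "",
    group = c("IncP-9 alpha", "IncP-9 beta"),
    seq = c(refA, refB))

  # identical query: label, distance 0, support 100
  cls <- classify_amplicons(recs(q1 = refA), references, n_reps = 50, seed = 2)
  expect_identical(cls$label, "IncP-9 alpha")
  expect_equal(cls$distance, 0)
  expect_equal(cls$support, 100)

  # far-away query (half the sites cycled to a different base) is unaffiliated
  farc <- strsplit(refA, "")[[1]]
  cyc <- c(A = "C", C = "G", G = "T", T = "A")
  farc[seq(1, 120, by = 2)] <- cyc[farc[seq(1, 120, by = 2)]]
  far <- paste(farc, collapse = "")
  clsf <- classify_amplicons(recs(q2 = far), references, n_reps = 20, seed = 2)
  expect_identical(clsf$label, "unaffiliated")
  expect_gt(clsf$distance, 0.10)

  expect_error(classify_amplicons(recs(q = refA)[0, ], references), "no queries")
  refs1 <- references; refs1$group <- "IncP-9 alpha"
  expect_error(classify_amplicons(recs(q = refA), refs1), "2 distinct labels")
})

test_that("equidistant queries break ties to the lowest-index reference", {
  base <- strrep("ACGT", 25)
  v <- function(pos, b) {
    s <- strsplit(base, "")[[1]]; s[pos] <- b; paste(s, collapse = "")
  }
  references <- tibble::tibble(
    id = c("r1", "r2"), description = "",
    group = c("IncP-9 alpha", "IncP-9 beta"),
    seq = c(v(1, "C"), v(5, "C")))
  # query equidistant (1 difference) from both references
  cls <- classify_amplicons(recs(q = base), references, n_reps = 200, seed = 4)
  expect_identical(cls$nearest_reference, "r1")
  expect_gt(cls$support, 25)
  expect_lt(cls$support, 75)
})

test_that("synthetic subgroup queries classify back to their subgroup", {
  panel <- simulate_panel(sim_config(seed = 29, seqs_per_subgroup = 2))
  q <- simulate_queries(panel, n_per_subgroup = 1, divergence = 0.02)
  refs <- amplicon_sequences(
    predict_amplicons(incp9_forward, incp9_reverse, panel$targets),
    panel$targets)
  cls <- classify_amplicons(q, refs, n_reps = 50, seed = 6)
  expect_identical(cls$label, q$group)
  expect_true(all(cls$distance <= 0.10))
})

test_that("newick output round-trips topology, lengths and labels", {
  d <- matrix(c(0, 2, 3, 3, 2, 0, 3, 3, 3, 3, 0, 2, 3, 3, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  txt <- write_newick(tr)
  back <- read_newick(text = txt)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-6)

  # quoted labels with spaces survive
  tr$tip.label <- c("pM3 like", "clone 7", "C", "D")
  txt2 <- write_newick(tr)
  back2 <- read_newick(text = txt2)
  expect_setequal(back2$tip.label, tr$tip.label)

  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tmp)
  expect_setequal(read_newick(tmp)$tip.label, tr$tip.label)
})
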