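# Distance-based phylogenetics: p-distance with pairwise deletion,
# Jukes-Cantor correction, neighbor-joining (Saitou-Nei agglomeration with
# the Studier-Keppler Q criterion), bootstrap supports over column
# resampling, and nearest-reference subgroup classification of amplicons.

#' Pairwise p-distance of an alignment
#'
#' Proportion of differing sites over the columns where both rows are
#' non-gap (pairwise deletion). Comparison is literal code inequality after
#' normalization: an ambiguity code is a difference unless identical.
#'
#' @param aln An alignment tibble (see [align_sequences()]).
#' @return A symmetric numeric matrix with zero diagonal, labelled by record
#'   id. Errors if any pair shares zero comparable columns.
#' @export
p_distance <- function(aln) {
  aln <- validate_alignment(aln)
  m <- encode_matrix(aln$seq)
  d <- pdist_cpp(m, seq_len(ncol(m)))
  dimnames(d) <- list(aln$id, aln$id)
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    stop(sprintf("no comparable columns between '%s' and '%s'",
                 aln$id[bad[1]], aln$id[bad[2]]), call. = FALSE)
  }
  d
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - 4p/3)` substitutions per site. Saturated
#' proportions (`p >= 0.75`) are an error, never silently clamped.
#'
#' @param p Numeric vector (or matrix) of mismatch proportions in
#'   `[0, 0.75)`.
#' @return Corrected distances, same shape as `p`.
#' @export
#' @examples
#' jc_correct(0.1)
jc_correct <- function(p) {
  if (any(p < 0)) stop("negative proportion", call. = FALSE)
  if (any(p >= 0.75)) {
    stop("saturated distance: p >= 0.75 has no Jukes-Cantor correction",
         call. = FALSE)
  }
  out <- -0.75 * log(1 - 4 * p / 3)
  out
}

#' Distance matrix of an alignment under a substitution model
#'
#' @param aln An alignment tibble.
#' @param model `"JC"` (Jukes-Cantor, default) or `"p"` (raw p-distance).
#' @return Symmetric labelled distance matrix.
#' @export
dist_matrix <- function(aln, model = c("JC", "p")) {
  model <- match.arg(model)
  p <- p_distance(aln)
  if (model == "p") p else jc_correct(p)
}

# ---- neighbor joining -------------------------------------------------------

# Shared agglomerator. Maintains original slot ids; at each step the
# Q-minimal active pair (ties: lowest active (row, col)) is joined and the
# merged cluster keeps the first slot. Returns the join list and, when
# building a tree, per-join branch lengths plus the final trifurcation.
nj_engine <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 3L)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  active <- seq_len(n)
  frag <- rownames(d)
  if (is.null(frag)) frag <- paste0("t", seq_len(n))
  frag <- newick_quote(frag)
  joins <- list()
  while (length(active) > 3L) {
    m <- length(active)
    dd <- d[active, active, drop = FALSE]
    R <- rowSums(dd)
    Q <- (m - 2) * dd - outer(R, R, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- idx[1]; j <- idx[2]
    li <- dd[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- dd[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    si <- active[i]; sj <- active[j]
    joins[[length(joins) + 1L]] <- c(si, sj)
    frag[si] <- sprintf("(%s:%s,%s:%s)", frag[si], fmt_bl(li),
                        frag[sj], fmt_bl(lj))
    dnew <- (d[si, active] + d[sj, active] - d[si, sj]) / 2
    d[si, active] <- dnew
    d[active, si] <- dnew
    d[si, si] <- 0
    active <- active[-j]
  }
  a <- active
  dd <- d[a, a, drop = FALSE]
  l1 <- max((dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2, 0)
  l2 <- max((dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2, 0)
  l3 <- max((dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2, 0)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[a[1]], fmt_bl(l1), frag[a[2]], fmt_bl(l2),
                    frag[a[3]], fmt_bl(l3))
  list(joins = joins, final = a, newick = newick)
}

# Join order for guide-tree use: continues past the trifurcation so exactly
# one cluster remains (the last three collapse lowest-slot-first).
nj_join_order <- function(d) {
  if (nrow(d) == 3L) {
    eng <- list(joins = list(), final = 1:3)
  } else {
    eng <- nj_engine(d)
  }
  a <- sort(eng$final)
  c(eng$joins, list(c(a[1], a[2]), c(a[1], a[3])))
}

fmt_bl <- function(x) {
  s <- sub("0+$", "", sprintf("%.8f", x))
  sub("\\.$", ".0", s)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion.
#' Tie-breaks take the lowest (row, col) index pair, and negative branch
#' lengths are clamped to zero, so the result is deterministic. The tree is
#' unrooted (basal trifurcation).
#'
#' @param d Symmetric distance matrix with zero diagonal and row/col names,
#'   at least 3 taxa.
#' @return An [ape::phylo] object.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  eng <- nj_engine(d)
  tr <- ape::read.tree(text = eng$newick)
  tr$tip.label <- newick_unquote(tr$tip.label)
  tr
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate under the same distance model, and annotates each internal
#' edge of the full-data tree with the percentage of replicates containing
#' its bipartition. Replicates index columns only, so supports do not
#' depend on row order; results are reproducible given `seed`.
#'
#' @param aln An alignment tibble with at least 4 rows.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @param model Distance model, `"JC"` or `"p"`.
#' @return An [ape::phylo] tree whose `node.label` holds integer percent
#'   supports (root/basal node label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 42L,
                              model = c("JC", "p")) {
  model <- match.arg(model)
  aln <- validate_alignment(aln)
  if (nrow(aln) < 4L) stop("bootstrap needs at least 4 rows", call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  # canonical row order (by id) so supports do not depend on input order
  aln <- aln[order(aln$id), ]
  m <- encode_matrix(aln$seq)
  rownames(m) <- aln$id
  C <- ncol(m)
  main <- nj_tree(named_dist(m, seq_len(C), aln$id, model))
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(C, C, replace = TRUE)
      nj_tree(named_dist(m, cols, aln$id, model))
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- as.character(round(100 * counts / n_reps))
  supp[1] <- ""  # basal trifurcation carries no split
  main$node.label <- supp
  main
}

named_dist <- function(m, cols, ids, model) {
  p <- pdist_cpp(m, as.integer(cols))
  if (anyNA(p)) {
    bad <- which(is.na(p), arr.ind = TRUE)[1, ]
    stop(sprintf("no comparable columns between '%s' and '%s'",
                 ids[bad[1]], ids[bad[2]]), call. = FALSE)
  }
  d <- if (model == "p") p else jc_correct(p)
  dimnames(d) <- list(ids, ids)
  d
}

# ---- subgroup classification ------------------------------------------------

#' Classify amplicon sequences into replicon subgroups
#'
#' Queries are co-aligned with the labelled references
#' ([align_sequences()]); each query is assigned the subgroup label of its
#' nearest reference by (default) Jukes-Cantor distance, or
#' `"unaffiliated"` when that distance exceeds `tau`. Support is the
#' percentage of bootstrap replicates (query-reference distances recomputed
#' on resampled columns) that reproduce the assigned label. Equidistant
#' references resolve to the lowest-index reference. Pairs whose distance
#' saturates (p >= 0.75) are treated as infinitely distant; a query
#' saturated against every reference is an error.
#'
#' @param queries Tibble of query records (`id`, `seq`).
#' @param references Tibble of reference records with a non-NA `group`
#'   column covering at least 2 distinct labels.
#' @param tau Distance threshold (substitutions/site) beyond which a query
#'   is reported `"unaffiliated"` (default 0.10).
#' @param n_reps Bootstrap replicates for the support value (default 100).
#' @param seed Integer RNG seed (default 42).
#' @param model `"JC"` or `"p"`.
#' @return A `subgroup_classification` object: a tibble with columns
#'   `query_id`, `label`, `nearest_reference`, `distance`, `support`, with
#'   the co-alignment and call parameters as attributes.
#' @export
classify_amplicons <- function(queries, references, tau = 0.10,
                               n_reps = 100L, seed = 42L,
                               model = c("JC", "p")) {
  model <- match.arg(model)
  queries <- as_records(queries)
  references <- as_records(references)
  if (nrow(queries) == 0L) stop("no queries", call. = FALSE)
  if (!("group" %in% names(references)) || anyNA(references$group)) {
    stop("references must all carry a group label", call. = FALSE)
  }
  if (length(unique(references$group)) < 2L) {
    stop("references must cover at least 2 distinct labels", call. = FALSE)
  }
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  all_rec <- dplyr::bind_rows(
    dplyr::mutate(references, .role = "reference"),
    dplyr::mutate(queries, .role = "query")
  )
  if (anyDuplicated(all_rec$id)) {
    stop("duplicate id across queries and references: ",
         all_rec$id[duplicated(all_rec$id)][1], call. = FALSE)
  }
  aln <- align_sequences(all_rec[, c("id", "description", "group", "seq")])
  m <- encode_matrix(aln$seq)
  qi <- which(all_rec$.role == "query")
  ri <- which(all_rec$.role == "reference")
  C <- ncol(m)

  qr_dist <- function(cols) {
    p <- pdist_cpp(m, as.integer(cols))[qi, ri, drop = FALSE]
    d <- p
    sat <- p >= 0.75 | is.na(p)
    d[!sat] <- if (model == "p") p[!sat] else jc_correct(p[!sat])
    d[sat] <- Inf
    d
  }
  nearest <- function(d) apply(d, 1, which.min)  # which.min = lowest index on ties

  d0 <- qr_dist(seq_len(C))
  if (any(apply(d0, 1, function(x) all(!is.finite(x))))) {
    bad <- which(apply(d0, 1, function(x) all(!is.finite(x))))[1]
    stop(sprintf("query '%s' has no comparable (unsaturated) columns against any reference",
                 queries$id[bad]), call. = FALSE)
  }
  hit <- nearest(d0)
  dist0 <- d0[cbind(seq_along(hit), hit)]
  label0 <- references$group[hit]

  agree <- matrix(0L, nrow = length(qi), ncol = n_reps)
  agree <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      cols <- sample.int(C, C, replace = TRUE)
      dr <- qr_dist(cols)
      ok <- apply(dr, 1, function(x) any(is.finite(x)))
      lab <- rep(NA_character_, length(qi))
      lab[ok] <- references$group[nearest(dr[ok, , drop = FALSE])]
      as.integer(!is.na(lab) & lab == label0)
    }, integer(length(qi)))
  })
  if (is.null(dim(agree))) agree <- matrix(agree, nrow = length(qi))
  support <- 100 * rowSums(agree) / n_reps

  out <- tibble(
    query_id = queries$id,
    label = ifelse(dist0 > tau, "unaffiliated", label0),
    nearest_reference = references$id[hit],
    distance = dist0,
    support = support
  )
  structure(out,
            class = c("subgroup_classification", class(out)),
            alignment = aln, tau = tau, n_reps = n_reps, seed = seed,
            model = model)
}

# ---- newick i/o -------------------------------------------------------------

newick_special <- "[\\s()\\[\\]{}/\\\\,;:=*'\"`+<>~]"

newick_quote <- function(x) {
  needs <- grepl(newick_special, x, perl = TRUE)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

newick_unquote <- function(x) {
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
  x
}

#' Write a tree in Newick format
#'
#' Branch lengths are written to 6 decimals; internal `node.label`s (e.g.
#' bootstrap supports) are emitted as internal labels. Labels containing
#' whitespace or Newick punctuation are single-quoted, and survive a
#' [read_newick()] round trip.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path (or `NULL` to return the string).
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  bl <- tree$edge.length
  node_lab <- tree$node.label
  lab_of <- function(node) {
    if (node <= n_tip) return(newick_quote(tree$tip.label[node]))
    if (is.null(node_lab)) return("")
    lab <- node_lab[node - n_tip]
    if (is.na(lab) || !nzchar(lab)) "" else newick_quote(lab)
  }
  build <- function(node) {
    es <- kids[[as.character(node)]]
    if (is.null(es)) return(lab_of(node))
    sub <- vapply(es, function(e) {
      s <- build(tree$edge[e, 2])
      if (!is.null(bl)) s <- sprintf("%s:%.6f", s, bl[e])
      s
    }, character(1))
    sprintf("(%s)%s", paste(sub, collapse = ","), lab_of(node))
  }
  txt <- paste0(build(root), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] with proper handling of single-quoted labels
#' (quotes stripped, embedded spaces preserved).
#'
#' @param path Path to a Newick file, or a literal string via `text`.
#' @param text Optional Newick string (overrides `path`).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  txt <- if (!is.null(text)) text else paste(readLines(path, warn = FALSE), collapse = "")
  # shelter quoted labels from ape's parser
  pat <- "'(?:[^']|'')*'"
  mt <- gregexpr(pat, txt, perl = TRUE)[[1]]
  repl <- character(0)
  if (mt[1] != -1L) {
    repl <- regmatches(txt, gregexpr(pat, txt, perl = TRUE))[[1]]
    for (k in seq_along(repl)) {
      txt <- sub(pat, sprintf("QLBL%dQ", k), txt, perl = TRUE)
    }
  }
  tr <- ape::read.tree(text = txt)
  restore <- function(labs) {
    for (k in seq_along(repl)) {
      labs[labs == sprintf("QLBL%dQ", k)] <- newick_unquote(repl[k])
    }
    labs
  }
  tr$tip.label <- restore(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- restore(tr$node.label)
  tr
}
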