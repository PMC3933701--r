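# Multiple alignment of replicon reference sets: a Needleman-Wunsch pairwise
# primitive and a progressive aligner over an NJ guide tree. Replicon
# backbones are close homologs, so linear gap costs are used throughout.

default_scores <- function() list(match = 1, mismatch = -1, gap = -2)

# equal-length gapped strings -> n x C integer mask matrix (0 = gap)
encode_matrix <- function(seqs, what = "alignment row") {
  rows <- lapply(seq_along(seqs), function(k) {
    encode_seq(seqs[k], allow_gap = TRUE, what = what)
  })
  lens <- lengths(rows)
  if (length(unique(lens)) > 1L) {
    stop("rows have unequal lengths: ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  }
  do.call(rbind, rows)
}

# character matrix (rows x cols) -> 5 x C column-fraction profile over
# (A, C, G, T, gap); degenerate residues are spread fractionally.
profile_from_matrix <- function(masks) {
  n <- nrow(masks)
  prof <- matrix(0, nrow = 5L, ncol = ncol(masks))
  for (b in 1:4) {
    bit <- c(1L, 2L, 4L, 8L)[b]
    sizes <- rowSums(outer(as.vector(masks), c(1L, 2L, 4L, 8L), bitwAnd) > 0L)
    w <- matrix(ifelse(masks > 0L & bitwAnd(masks, bit) > 0L,
                       1 / pmax(sizes, 1L), 0), nrow = n)
    prof[b, ] <- colSums(w)
  }
  prof[5L, ] <- colSums(masks == 0L)
  prof / n
}

#' Remove gap characters from sequences
#'
#' @param x Character vector of possibly gapped sequences.
#' @return Character vector with `-` and `.` removed.
#' @export
degap <- function(x) gsub("[-.]", "", x)

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with linear gap penalty. Degenerate bases score as a
#' match iff their expansions intersect (alignment, unlike primer matching,
#' is symmetric). Traceback ties break diagonal > up > left, so the result
#' is deterministic.
#'
#' @param a,b Ungapped nucleotide strings (IUPAC alphabet). One of the two
#'   may be empty, not both.
#' @param match,mismatch,gap Scoring parameters (linear gaps).
#' @return A one-row tibble with columns `aligned_a`, `aligned_b`, `score`.
#' @export
#' @examples
#' pairwise_align("ACGT", "AGT")
pairwise_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) && !nzchar(b)) {
    stop("both sequences are empty", call. = FALSE)
  }
  ea <- if (nzchar(a)) encode_seq(a, what = "sequence a") else integer(0)
  eb <- if (nzchar(b)) encode_seq(b, what = "sequence b") else integer(0)
  al <- nw_pair_cpp(ea, eb, match, mismatch, gap)
  ca <- c(strsplit(a, "")[[1]], "-")
  cb <- c(strsplit(b, "")[[1]], "-")
  tibble(
    aligned_a = paste(ca[ifelse(al$ai == 0L, length(ca), al$ai)], collapse = ""),
    aligned_b = paste(cb[ifelse(al$bi == 0L, length(cb), al$bi)], collapse = ""),
    score = al$score
  )
}

#' Progressive multiple alignment
#'
#' Aligns the (ungapped) input records progressively: pairwise
#' Needleman-Wunsch distances feed a neighbor-joining guide tree, and
#' cluster profiles are merged in agglomeration order by profile-profile
#' alignment. Deterministic given input order; two records reduce to
#' [pairwise_align()].
#'
#' @param records Tibble of sequence records (`id`, `seq`, optionally
#'   `description`, `group`) or a named character vector.
#' @param match,mismatch,gap Scoring parameters.
#' @return An alignment: the input tibble with gapped, equal-length `seq`
#'   rows, in the original record order.
#' @export
align_sequences <- function(records, match = 1, mismatch = -1, gap = -2) {
  records <- as_records(records)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to align", call. = FALSE)
  if (anyDuplicated(records$id)) {
    stop("duplicate record id: ", records$id[duplicated(records$id)][1],
         call. = FALSE)
  }
  seqs <- degap(records$seq)
  enc <- lapply(seqs, encode_seq, allow_gap = FALSE, what = "record")

  if (n == 2L) {
    pa <- pairwise_align(seqs[1], seqs[2], match, mismatch, gap)
    out <- records
    out$seq <- c(pa$aligned_a, pa$aligned_b)
    return(validate_alignment(out))
  }

  # guide distances: 1 - identity over pairwise-aligned columns
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- nw_guide_dist_cpp(enc[[i]], enc[[j]],
                                              match, mismatch, gap)
    }
  }

  joins <- nj_join_order(d)
  # clusters hold row indices and their current gapped character matrices
  clusters <- lapply(1:n, function(k) {
    list(rows = k, mat = matrix(strsplit(seqs[k], "")[[1]], nrow = 1))
  })
  for (jn in joins) {
    a <- clusters[[jn[1]]]; b <- clusters[[jn[2]]]
    pa <- profile_from_matrix(encode_matrix(apply(a$mat, 1, paste, collapse = "")))
    pb <- profile_from_matrix(encode_matrix(apply(b$mat, 1, paste, collapse = "")))
    al <- nw_profile_cpp(pa, pb, match, mismatch, gap)
    ga <- cbind(a$mat, "-")[, ifelse(al$ai == 0L, ncol(a$mat) + 1L, al$ai),
                            drop = FALSE]
    gb <- cbind(b$mat, "-")[, ifelse(al$bi == 0L, ncol(b$mat) + 1L, al$bi),
                            drop = FALSE]
    clusters[[jn[1]]] <- list(rows = c(a$rows, b$rows), mat = rbind(ga, gb))
    clusters[[jn[2]]] <- NULL_cluster()
  }
  final <- clusters[[which(vapply(clusters, function(cl) length(cl$rows) > 0L,
                                  logical(1)))[1]]]
  aligned <- character(n)
  aligned[final$rows] <- apply(final$mat, 1, paste, collapse = "")
  out <- records
  out$seq <- aligned
  validate_alignment(out)
}

NULL_cluster <- function() list(rows = integer(0), mat = matrix(character(0), 0, 0))

# coerce inputs to a records tibble
as_records <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(new_records(ids, "", NA_character_, unname(x)))
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  as_tibble(x)
}

#' Validate an alignment tibble
#'
#' Checks that all rows have equal length, that there are at least two rows,
#' and that every character is a gap or IUPAC code.
#'
#' @param aln Tibble of gapped records.
#' @return `aln`, invisibly classed, after validation.
#' @export
validate_alignment <- function(aln) {
  aln <- as_records(aln)
  if (nrow(aln) < 2L) stop("an alignment needs at least 2 rows", call. = FALSE)
  widths <- nchar(aln$seq)
  if (length(unique(widths)) > 1L) {
    off <- aln$id[widths != widths[1]][1]
    stop("ragged alignment: record '", off, "' has length ",
         widths[widths != widths[1]][1], ", expected ", widths[1],
         call. = FALSE)
  }
  for (k in seq_len(nrow(aln))) {
    encode_seq(aln$seq[k], allow_gap = TRUE,
               what = paste0("record '", aln$id[k], "'"))
  }
  aln
}

#' Number of columns in an alignment
#' @param aln An alignment tibble.
#' @return Integer column count.
#' @export
alignment_width <- function(aln) {
  w <- unique(nchar(aln$seq))
  stopifnot(length(w) == 1L)
  w
}

#' Read a pre-computed (gapped FASTA) alignment
#'
#' @param path Path to a gapped FASTA file with equal-length rows.
#' @return An alignment tibble.
#' @export
read_alignment <- function(path) {
  validate_alignment(read_fasta(path))
}

#' Write an alignment as gapped FASTA
#' @param aln An alignment tibble.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70L) {
  write_fasta(validate_alignment(aln), path, width = width)
}
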