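#' @useDynLib reptype, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# ---- IUPAC degenerate-alphabet algebra --------------------------------------

# bitmask encoding: A=1, C=2, G=4, T=8; ambiguity codes are unions.
.iupac_mask <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # G/C
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)
.mask_code <- character(15L)
.mask_code[.iupac_mask] <- names(.iupac_mask)

.gap_chars <- c("-", ".")

#' IUPAC nucleotide codes and their expansions
#'
#' @return A tibble with one row per IUPAC code: the code, its expansion
#'   (concrete bases it stands for), and the expansion size.
#' @export
#' @examples
#' iupac_codes()
iupac_codes <- function() {
  tibble(
    code = names(.iupac_mask),
    expansion = vapply(.iupac_mask, function(m) {
      paste(c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L],
            collapse = "")
    }, character(1)),
    size = nchar(vapply(.iupac_mask, function(m) {
      paste(c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L],
            collapse = "")
    }, character(1)))
  )
}

# Encode a nucleotide string into an integer mask vector. Gaps become 0 when
# allow_gap, otherwise error. Unknown characters always error.
encode_seq <- function(x, allow_gap = FALSE, what = "sequence") {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- unname(.iupac_mask[chars])
  bad <- is.na(m) & !(chars %in% .gap_chars)
  if (any(bad)) {
    stop(sprintf("illegal character '%s' at position %d in %s",
                 chars[which(bad)[1]], which(bad)[1], what), call. = FALSE)
  }
  m[is.na(m)] <- 0L
  if (!allow_gap && any(m == 0L)) {
    stop(sprintf("gap character at position %d in %s (gaps not allowed here)",
                 which(m == 0L)[1], what), call. = FALSE)
  }
  m
}

decode_seq <- function(masks) {
  out <- character(length(masks))
  out[masks == 0L] <- "-"
  out[masks > 0L] <- .mask_code[masks[masks > 0L]]
  paste(out, collapse = "")
}

#' Reverse complement of (possibly degenerate) nucleotide strings
#'
#' The complement table extends to IUPAC ambiguity codes (R<->Y, K<->M,
#' B<->V, D<->H; W, S and N are self-complementary). Vectorised.
#'
#' @param x Character vector of nucleotide strings over the IUPAC alphabet,
#'   without gaps.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("GAGGGTTTGGAGATCATWAGA")
reverse_complement <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    m <- encode_seq(s, allow_gap = FALSE, what = "reverse_complement input")
    # complement a 4-bit mask: swap A<->T bits and C<->G bits
    comp <- bitwOr(
      bitwOr(ifelse(bitwAnd(m, 1L) > 0L, 8L, 0L),
             ifelse(bitwAnd(m, 8L) > 0L, 1L, 0L)),
      bitwOr(ifelse(bitwAnd(m, 2L) > 0L, 4L, 0L),
             ifelse(bitwAnd(m, 4L) > 0L, 2L, 0L))
    )
    decode_seq(rev(comp))
  }, character(1), USE.NAMES = FALSE)
}

#' Degeneracy of a primer sequence
#'
#' The number of concrete oligo species a degenerate design stands for:
#' the product over positions of the IUPAC expansion sizes.
#'
#' @param x Character vector of degenerate primer sequences (no gaps).
#' @return Numeric vector of degeneracies (all >= 1; numeric because a
#'   highly ambiguous window can exceed integer range).
#' @export
#' @examples
#' degeneracy(c("ACGT", "NN", "GAGGGTTTGGAGATCATWAGA"))
degeneracy <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(1)
    m <- encode_seq(s, allow_gap = FALSE, what = "primer")
    sizes <- rowSums(outer(m, c(1L, 2L, 4L, 8L), bitwAnd) > 0L)
    prod(sizes)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Enumerate the concrete expansions of a degenerate primer
#'
#' @param x A single degenerate nucleotide string.
#' @return Character vector of all concrete (ACGT-only) expansions, in
#'   lexicographic position order.
#' @export
#' @examples
#' expand_primer("ATW")
expand_primer <- function(x) {
  stopifnot(length(x) == 1L)
  m <- encode_seq(x, allow_gap = FALSE, what = "primer")
  sets <- lapply(m, function(b) c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L])
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

#' Does a primer base cover a target base?
#'
#' Subset rule: a (possibly ambiguous) target base matches iff every
#' concretization of the target lies inside the primer base's expansion.
#' An `N` in a target therefore only matches a primer `N`, while a primer `W`
#' matches targets `A`, `T` and `W`. Vectorised over pairs.
#'
#' @param primer_base,target_base Character vectors of single IUPAC codes
#'   (no gaps), recycled to a common length.
#' @return Logical vector.
#' @export
#' @examples
#' base_match("W", c("A", "C", "N"))
base_match <- function(primer_base, target_base) {
  n <- max(length(primer_base), length(target_base))
  p <- rep_len(toupper(primer_base), n)
  t <- rep_len(toupper(target_base), n)
  pm <- .iupac_mask[p]
  tm <- .iupac_mask[t]
  if (anyNA(pm) || anyNA(tm)) {
    bad <- c(p[is.na(pm)], t[is.na(tm)])[1]
    stop(sprintf("'%s' is not a gap-free IUPAC nucleotide code", bad),
         call. = FALSE)
  }
  unname(bitwAnd(tm, bitwNot(pm)) == 0L)
}

# ---- FASTA records ----------------------------------------------------------

new_records <- function(id, description = "", group = NA_character_, seq) {
  tibble(id = id, description = description, group = group, seq = seq)
}

#' Read sequence records from a FASTA file
#'
#' Residues are uppercased and `U` is mapped to `T`. Headers of the form
#' `>id free text group=<label>` populate the `group` column (replicon
#' subgroup labels such as `"IncP-9 alpha"` when quoted as `group="..."` or
#' the remainder of the header after `group=`).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines; gapped
#'   rows are accepted).
#' @return A tibble with columns `id`, `description`, `group`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^;", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(new_records(character(), character(), character(), character())[0, ])
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop(sprintf("malformed FASTA: line %d does not start a record", lineno[1]),
         call. = FALSE)
  }
  rec_idx <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  hdr_lineno <- lineno[is_hdr]
  if (any(!nzchar(trimws(headers)))) {
    stop(sprintf("malformed header at line %d: empty id",
                 hdr_lineno[which(!nzchar(trimws(headers)))[1]]), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S+\\s*", "", headers))
  group <- rep(NA_character_, length(headers))
  has_group <- grepl("group=", desc, fixed = TRUE)
  gval <- sub('^.*group=', "", desc[has_group])
  gval <- ifelse(grepl('^"', gval), sub('^"([^"]*)".*$', "\\1", gval),
                 sub("\\s.*$", "", gval))
  group[has_group] <- gval
  desc <- trimws(sub('\\s*group=.*$', "", desc))

  bodies <- vapply(seq_along(headers), function(k) {
    paste(lines[rec_idx == k & !is_hdr], collapse = "")
  }, character(1))
  bodies <- chartr("u", "U", bodies)
  bodies <- gsub("U", "T", toupper(bodies), fixed = TRUE)
  # validate characters, reporting the file line of the offender
  for (k in seq_along(bodies)) {
    chars <- strsplit(bodies[k], "", fixed = TRUE)[[1]]
    ok <- chars %in% c(names(.iupac_mask), .gap_chars)
    if (!all(ok)) {
      body_lines <- lines[rec_idx == k & !is_hdr]
      body_lineno <- lineno[rec_idx == k & !is_hdr]
      offset <- which(!ok)[1]
      cum <- cumsum(nchar(body_lines))
      lno <- body_lineno[which(cum >= offset)[1]]
      stop(sprintf("illegal character '%s' in record '%s' at line %d",
                   chars[offset], ids[k], lno), call. = FALSE)
    }
    if (!nzchar(bodies[k])) {
      stop(sprintf("record '%s' (line %d) has an empty sequence",
                   ids[k], hdr_lineno[k]), call. = FALSE)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  new_records(ids, desc, group, bodies)
}

#' Write sequence records to a FASTA file
#'
#' Inverse of [read_fasta()]: a `group` label is serialised back into the
#' header as `group="<label>"`.
#'
#' @param records Tibble with columns `id`, `seq` and optionally
#'   `description`, `group`.
#' @param path Output path.
#' @param width Line-wrap width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  group <- if ("group" %in% names(records)) records$group else NA_character_
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    hdr <- records$id[k]
    if (!is.na(desc[k]) && nzchar(desc[k])) hdr <- paste(hdr, desc[k])
    if (!is.na(group[k])) hdr <- sprintf('%s group="%s"', hdr, group[k])
    writeLines(paste0(">", hdr), con)
    s <- records$seq[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- primer registry --------------------------------------------------------

#' The published IncP-9 oriV-rep primer system
#'
#' The degenerate 21-mer pair targeting the oriV-rep region of the nine
#' IncP-9 subgroups, with its expected product-size window of 610-637 bp.
#'
#' @return A tibble with columns `name`, `sequence`, `role`, `product_min`,
#'   `product_max`.
#' @export
#' @examples
#' incp9_primers()
incp9_primers <- function() {
  tibble(
    name = c("IncP9-oriV-rep-F", "IncP9-oriV-rep-R"),
    sequence = c("GAGGGTTTGGAGATCATWAGA", "GGTCTGTATCCAGTTRTGCTT"),
    role = c("forward", "reverse"),
    product_min = 610L,
    product_max = 637L
  )
}

#' Reference accession panels for the IncP-9 oriV-rep system
#'
#' The GenBank accessions of the 28 oriV and 28 rep replicon reference
#' sequences the IncP-9 system was designed on, plus the accession range of
#' the cloned environmental amplicons. Sequences are not bundled; fetch them
#' by accession and pass them as a reference FASTA.
#'
#' @param set One of `"oriV"`, `"rep"` or `"amplicon_clones"`.
#' @return Character vector of accession numbers.
#' @export
#' @examples
#' length(incp9_accessions("oriV"))
incp9_accessions <- function(set = c("oriV", "rep", "amplicon_clones")) {
  set <- match.arg(set)
  acc <- switch(set,
    oriV = "EU499619-EU499641, AF078924, AB237655, AJ344068, AB257759, AF491307",
    rep = "EU499644-EU499666, AF078924, AB237655, AJ344068, AB257760, AF491307",
    amplicon_clones = "KF706553-KF706633"
  )
  expand_accessions(acc)
}

#' Expand a comma-separated accession list with ranges
#'
#' Ranges like `"EU499619-EU499641"` are expanded inclusively; the two
#' endpoints must share a prefix and numeric width.
#'
#' @param x A single string of comma-separated accessions and ranges.
#' @return Character vector of individual accessions.
#' @export
#' @examples
#' expand_accessions("EU499619-EU499621, AF078924")
expand_accessions <- function(x) {
  stopifnot(length(x) == 1L)
  parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  out <- lapply(parts, function(p) {
    if (!grepl("-", p, fixed = TRUE)) return(p)
    ends <- trimws(strsplit(p, "-", fixed = TRUE)[[1]])
    if (length(ends) != 2L) stop("malformed accession range: ", p, call. = FALSE)
    pre <- sub("[0-9]+$", "", ends)
    num <- sub("^.*?([0-9]+)$", "\\1", ends)
    if (pre[1] != pre[2] || nchar(num[1]) != nchar(num[2])) {
      stop("malformed accession range: ", p, call. = FALSE)
    }
    sprintf("%s%0*d", pre[1], nchar(num[1]),
            seq(as.integer(num[1]), as.integer(num[2])))
  })
  unlist(out, use.names = FALSE)
}

#' Read a primer registry file
#'
#' A flat key-value registry (Debian-control format: blank-line-separated
#' blocks of `key: value` lines) describing externally defined primer
#' systems, e.g. the trfA (IncP-1) or IncP-7 rep systems. Recognised keys:
#' `name`, `sequence`, `role` (`forward`/`reverse`), optional `product_min`,
#' `product_max`.
#'
#' @param path Registry file path.
#' @return A tibble with columns `name`, `sequence`, `role`, `product_min`,
#'   `product_max`.
#' @export
read_primer_registry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  req <- c("name", "sequence", "role")
  if (!all(req %in% names(d))) {
    stop("primer registry must define keys: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  d$sequence <- toupper(gsub("[ \t]", "", d$sequence))
  d$role <- tolower(d$role)
  if (!all(d$role %in% c("forward", "reverse"))) {
    stop("primer role must be 'forward' or 'reverse'", call. = FALSE)
  }
  for (k in seq_len(nrow(d))) {
    encode_seq(d$sequence[k], allow_gap = FALSE,
               what = paste0("primer '", d$name[k], "'"))
  }
  tibble(
    name = d$name,
    sequence = d$sequence,
    role = d$role,
    product_min = if ("product_min" %in% names(d)) as.integer(d$product_min) else NA_integer_,
    product_max = if ("product_max" %in% names(d)) as.integer(d$product_max) else NA_integer_
  )
}
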