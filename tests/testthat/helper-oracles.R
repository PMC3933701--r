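# Independent oracles used across the suite. They deliberately avoid the
# package's own IUPAC tables and scanning code: expansions come from
# Biostrings' IUPAC map, and the scanners/aligners are naive R loops.

iupac_expand_oracle <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[toupper(code)]], "")[[1]]
}

base_match_oracle <- function(primer_base, target_base) {
  all(iupac_expand_oracle(target_base) %in% iupac_expand_oracle(primer_base))
}

degeneracy_oracle <- function(primer) {
  length(expand_oracle(primer))
}

# brute-force enumeration of concrete expansions
expand_oracle <- function(primer) {
  sets <- lapply(strsplit(primer, "")[[1]], iupac_expand_oracle)
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

tm_wallace_oracle <- function(primer) {
  exps <- expand_oracle(primer)
  mean(vapply(exps, function(e) {
    b <- strsplit(e, "")[[1]]
    2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
  }, numeric(1)))
}

rc_oracle <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# naive position-by-position binding-site finder (plus strand of `primer`
# and of its reverse complement), mirroring the accepted-site rules
naive_find_sites <- function(primer, subject, anchor_len, max_mismatch) {
  L <- nchar(primer)
  n <- nchar(subject)
  res <- list()
  scan1 <- function(p, anchor_from_left, strand) {
    pb <- strsplit(p, "")[[1]]
    for (s in seq_len(max(n - L + 1L, 0L))) {
      tb <- strsplit(substr(subject, s, s + L - 1L), "")[[1]]
      ok <- mapply(base_match_oracle, pb, tb)
      mm <- sum(!ok)
      run <- 0L
      idx <- if (anchor_from_left) seq_len(L) else rev(seq_len(L))
      for (i in idx) {
        if (ok[i]) run <- run + 1L else break
      }
      if (run >= anchor_len && mm <= max_mismatch) {
        res[[length(res) + 1L]] <<- data.frame(
          strand = strand, start = s, end = s + L - 1L,
          n_mismatch = mm, anchor_run = run
        )
      }
    }
  }
  scan1(primer, FALSE, "+")
  scan1(rc_oracle(primer), TRUE, "-")
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), n_mismatch = integer(),
                      anchor_run = integer()))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small helper: records tibble from named character vector
recs <- function(...) {
  x <- c(...)
  tibble::tibble(id = names(x), description = "", group = NA_character_,
                 seq = unname(x))
}

incp9_forward <- "GAGGGTTTGGAGATCATWAGA"
incp9_reverse <- "GGTCTGTATCCAGTTRTGCTT"
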