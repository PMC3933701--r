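# Degenerate primer design: conservation profiling of a grouped alignment,
# enumeration of candidate windows under explicit constraints, per-target
# validation (3' anchor + mismatch budget), and pairing/ranking by amplicon
# size window.

#' Primer design constraints
#'
#' Defaults reflect the IncP-9 oriV-rep system: 21-mer primers with
#' degeneracy at most 8, a perfect 12 bp 3' anchor on every target, at most
#' 4 mismatches (all 5' of the anchor), and a 610-637 bp product across the
#' panel. `tm_min`/`tm_max` bound the Wallace-rule melting estimate; the
#' default 55-65 degC window brackets annealing near 53 degC.
#'
#' @param primer_length Primer length in nt (default 21).
#' @param max_degeneracy Maximum number of concrete expansions (default 8).
#' @param anchor_len Perfect-match run required at the 3' end, nt
#'   (default 12).
#' @param max_mismatch Mismatch budget outside the anchor (default 4; zero
#'   mismatches also passes).
#' @param amplicon_min,amplicon_max Product-size window in bp
#'   (defaults 610, 637).
#' @param max_gap_fraction Maximum per-column gap fraction admissible in a
#'   primer window (default 0: primer sites must be indel-free).
#' @param f_min Minimum base frequency a consensus must cover (default 0:
#'   every observed base).
#' @param tm_min,tm_max Wallace-rule melting-temperature window in degC.
#' @return A `primer_constraints` list.
#' @export
primer_constraints <- function(primer_length = 21L, max_degeneracy = 8L,
                               anchor_len = 12L, max_mismatch = 4L,
                               amplicon_min = 610L, amplicon_max = 637L,
                               max_gap_fraction = 0, f_min = 0,
                               tm_min = 55, tm_max = 65) {
  stopifnot(
    primer_length >= 1L, anchor_len >= 0L, anchor_len <= primer_length,
    max_degeneracy >= 1L, max_mismatch >= 0L,
    amplicon_min >= 2L * primer_length, amplicon_max >= amplicon_min,
    max_gap_fraction >= 0, max_gap_fraction <= 1,
    f_min >= 0, f_min <= 1, tm_min <= tm_max
  )
  structure(list(
    primer_length = as.integer(primer_length),
    max_degeneracy = as.integer(max_degeneracy),
    anchor_len = as.integer(anchor_len),
    max_mismatch = as.integer(max_mismatch),
    amplicon_min = as.integer(amplicon_min),
    amplicon_max = as.integer(amplicon_max),
    max_gap_fraction = max_gap_fraction,
    f_min = f_min, tm_min = tm_min, tm_max = tm_max
  ), class = "primer_constraints")
}

#' Wallace-rule melting temperature of a degenerate primer
#'
#' `2(A+T) + 4(G+C)` with base counts averaged over the primer's concrete
#' expansions (equivalently: per-position expected A/T weight). Vectorised.
#'
#' @param x Character vector of primer sequences.
#' @return Numeric vector, degrees C.
#' @export
#' @examples
#' tm_wallace("ACGT")
tm_wallace <- function(x) {
  vapply(x, function(s) {
    m <- encode_seq(s, what = "primer")
    sizes <- rowSums(outer(m, c(1L, 2L, 4L, 8L), bitwAnd) > 0L)
    at <- rowSums(outer(m, c(1L, 8L), bitwAnd) > 0L)  # A and T bits
    w_at <- at / sizes
    sum(2 * w_at + 4 * (1 - w_at))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-column conservation profile of an alignment
#'
#' Counts bases over A/C/G/T per column (degenerate residues contribute
#' fractionally across their expansion), the gap fraction, and a consensus
#' IUPAC code: the minimal code covering every base whose frequency among
#' non-gap residues is at least `f_min` (with `f_min = 0`, every observed
#' base, including the full expansion of any ambiguity code). Columns where
#' no base reaches `f_min` fall back to the majority base; all-gap columns
#' get an `NA` consensus.
#'
#' @param aln An alignment tibble.
#' @param f_min Minimum covered base frequency in `[0, 1]`.
#' @return Tibble with columns `column`, `n_A`, `n_C`, `n_G`, `n_T`,
#'   `gap_fraction`, `consensus`.
#' @export
conservation_profile <- function(aln, f_min = 0) {
  aln <- validate_alignment(aln)
  m <- encode_matrix(aln$seq)
  n <- nrow(m)
  sizes <- matrix(rowSums(outer(as.vector(m), c(1L, 2L, 4L, 8L), bitwAnd) > 0L),
                  nrow = n)
  counts <- vapply(c(1L, 2L, 4L, 8L), function(bit) {
    colSums(matrix(ifelse(m > 0L & bitwAnd(m, bit) > 0L, 1 / pmax(sizes, 1L), 0),
                   nrow = n))
  }, numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  nongap <- colSums(m > 0L)
  gap_fraction <- 1 - nongap / n
  # observed sets: union of expansions; frequency of a base = (rows whose
  # expansion contains it, weighted fractionally) / non-gap rows
  consensus <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (nongap[j] == 0L) return(NA_character_)
    if (f_min == 0) {
      # cover every observed base, including the full expansion of any
      # ambiguity code a row may carry
      mask <- Reduce(bitwOr, col[col > 0L])
    } else {
      freq <- counts[j, ] / nongap[j]
      keep <- freq >= f_min
      if (!any(keep)) keep <- freq == max(freq)
      mask <- sum(c(1L, 2L, 4L, 8L)[keep])
    }
    .mask_code[mask]
  }, character(1))
  tibble(
    column = seq_len(ncol(m)),
    n_A = counts[, 1], n_C = counts[, 2], n_G = counts[, 3], n_T = counts[, 4],
    gap_fraction = gap_fraction,
    consensus = consensus
  )
}

#' Validate a candidate primer against every target
#'
#' For each (ungapped) target the best binding site in the orientation
#' implied by `role` is chosen by fewest mismatches, then longest anchor,
#' then leftmost position, and judged against the anchor and mismatch
#' constraints. Targets shorter than the primer fail with reason
#' `"too short"`.
#'
#' @param sequence Candidate primer (5'->3') degenerate string.
#' @param targets Tibble of ungapped target records.
#' @param constraints A [primer_constraints()] list.
#' @param role `"forward"` or `"reverse"`.
#' @return Tibble with one row per target: `target_id`, `start`, `end`,
#'   `n_mismatch`, `anchor_run`, `pass`, `reason`.
#' @export
validate_candidate <- function(sequence, targets,
                               constraints = primer_constraints(),
                               role = c("forward", "reverse")) {
  role <- match.arg(role)
  targets <- as_records(targets)
  pe <- encode_seq(sequence, what = "candidate")
  L <- length(pe)
  strand <- if (role == "forward") "+" else "-"
  rows <- lapply(seq_len(nrow(targets)), function(k) {
    s <- degap(targets$seq[k])
    se <- encode_seq(s, what = paste0("target '", targets$id[k], "'"))
    if (length(se) < L) {
      return(tibble(target_id = targets$id[k], start = NA_integer_,
                    end = NA_integer_, n_mismatch = NA_integer_,
                    anchor_run = NA_integer_, pass = FALSE,
                    reason = "too short"))
    }
    w <- scan_one(pe, se, strand)
    best <- order(w[, 2], -w[, 3], w[, 1])[1]
    pass <- w[best, 3] >= constraints$anchor_len &&
      w[best, 2] <= constraints$max_mismatch
    tibble(target_id = targets$id[k], start = w[best, 1],
           end = w[best, 1] + L - 1L, n_mismatch = w[best, 2],
           anchor_run = w[best, 3], pass = pass,
           reason = if (pass) "" else "anchor/mismatch")
  })
  dplyr::bind_rows(rows)
}

#' Enumerate validated candidate primers over a conservation profile
#'
#' Slides a `primer_length` window over every run of consecutive
#' admissible columns (gap fraction at most `max_gap_fraction`), takes the
#' window consensus (reverse-complemented for `role = "reverse"`), and
#' keeps candidates whose degeneracy and Wallace Tm pass the constraints
#' and that validate against every target. Returns an empty tibble (with a
#' message) when no admissible window exists.
#'
#' @param profile Output of [conservation_profile()].
#' @param aln The alignment the profile was computed from (its degapped
#'   rows are the validation targets).
#' @param constraints A [primer_constraints()] list.
#' @param role `"forward"` or `"reverse"`.
#' @return Tibble with columns `window_start`, `window_end` (alignment
#'   columns), `sequence`, `role`, `degeneracy`, `tm`, `max_mismatch_obs`,
#'   `min_anchor_obs`, `per_target` (list of validation tibbles).
#' @export
enumerate_candidates <- function(profile, aln,
                                 constraints = primer_constraints(),
                                 role = c("forward", "reverse")) {
  role <- match.arg(role)
  aln <- validate_alignment(aln)
  targets <- aln
  targets$seq <- degap(targets$seq)
  L <- constraints$primer_length
  empty <- tibble(window_start = integer(), window_end = integer(),
                  sequence = character(), role = character(),
                  degeneracy = integer(), tm = numeric(),
                  max_mismatch_obs = integer(), min_anchor_obs = integer(),
                  per_target = list())
  adm <- which(profile$gap_fraction <= constraints$max_gap_fraction &
                 !is.na(profile$consensus))
  if (length(adm) < L) {
    message("no admissible window: fewer than ", L,
            " columns satisfy max_gap_fraction = ",
            constraints$max_gap_fraction)
    return(empty)
  }
  # windows of L consecutive admissible columns
  runs <- split(adm, cumsum(c(1L, diff(adm) != 1L)))
  wins <- list()
  for (r in runs) {
    if (length(r) < L) next
    for (s in 1:(length(r) - L + 1L)) {
      wins[[length(wins) + 1L]] <- r[s:(s + L - 1L)]
    }
  }
  if (length(wins) == 0L) {
    message("no admissible window: no gap-admissible run of length ", L)
    return(empty)
  }
  rows <- lapply(wins, function(cols) {
    cons <- paste(profile$consensus[cols], collapse = "")
    deg <- degeneracy(cons)
    if (deg > constraints$max_degeneracy) return(NULL)
    seq5to3 <- if (role == "forward") cons else reverse_complement(cons)
    tm <- tm_wallace(seq5to3)
    if (tm < constraints$tm_min || tm > constraints$tm_max) return(NULL)
    rep <- validate_candidate(seq5to3, targets, constraints, role)
    if (!all(rep$pass)) return(NULL)
    tibble(window_start = cols[1], window_end = cols[L],
           sequence = seq5to3, role = role, degeneracy = deg, tm = tm,
           max_mismatch_obs = max(rep$n_mismatch),
           min_anchor_obs = min(rep$anchor_run),
           per_target = list(rep))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    message("no candidate passed degeneracy/Tm/validation constraints (",
            length(wins), " windows examined)")
    return(empty)
  }
  out
}

#' Pair and rank validated forward/reverse candidates
#'
#' Keeps pairs whose per-target product length (reverse-site end minus
#' forward-site start, plus one) lies in the amplicon window for every
#' target, ranked by maximum pair degeneracy, then total mismatches over
#' all targets, then Tm difference, then leftmost forward window.
#'
#' @param forward,reverse Candidate tibbles from [enumerate_candidates()].
#' @param constraints A [primer_constraints()] list.
#' @return Tibble of pairs: forward/reverse window coordinates and
#'   sequences, `amplicon_min_obs`, `amplicon_max_obs`, `max_degeneracy`,
#'   `total_mismatch`, `tm_delta`, `per_target` (list: per-target amplicon
#'   lengths), best pair first.
#' @export
pair_primers <- function(forward, reverse, constraints = primer_constraints()) {
  if (nrow(forward) == 0L || nrow(reverse) == 0L) {
    return(tibble(fwd_window_start = integer(), fwd_window_end = integer(),
                  fwd_sequence = character(), rev_window_start = integer(),
                  rev_window_end = integer(), rev_sequence = character(),
                  amplicon_min_obs = integer(), amplicon_max_obs = integer(),
                  max_degeneracy = integer(), total_mismatch = integer(),
                  tm_delta = numeric(), per_target = list()))
  }
  rows <- list()
  for (i in seq_len(nrow(forward))) {
    for (j in seq_len(nrow(reverse))) {
      f <- forward[i, ]; r <- reverse[j, ]
      ft <- f$per_target[[1]]; rt <- r$per_target[[1]]
      stopifnot(identical(ft$target_id, rt$target_id))
      len <- rt$end - ft$start + 1L
      if (any(is.na(len)) || any(len < constraints$amplicon_min) ||
          any(len > constraints$amplicon_max)) next
      rows[[length(rows) + 1L]] <- tibble(
        fwd_window_start = f$window_start, fwd_window_end = f$window_end,
        fwd_sequence = f$sequence,
        rev_window_start = r$window_start, rev_window_end = r$window_end,
        rev_sequence = r$sequence,
        amplicon_min_obs = min(len), amplicon_max_obs = max(len),
        max_degeneracy = max(f$degeneracy, r$degeneracy),
        total_mismatch = sum(ft$n_mismatch) + sum(rt$n_mismatch),
        tm_delta = abs(f$tm - r$tm),
        per_target = list(tibble(target_id = ft$target_id,
                                 fwd_start = ft$start, rev_end = rt$end,
                                 amplicon_length = len))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(pair_primers(forward[0, ], reverse[0, ], constraints))
  dplyr::arrange(out, .data$max_degeneracy, .data$total_mismatch,
                 .data$tm_delta, .data$fwd_window_start)
}

#' Design degenerate primer pairs for a grouped reference panel
#'
#' End-to-end designer: aligns the records if they are not already aligned,
#' profiles conservation, enumerates forward and reverse candidates, and
#' pairs/ranks them under the amplicon-size window.
#'
#' @param records Tibble of reference records; treated as a pre-computed
#'   alignment when all rows have equal length and any contains a gap,
#'   otherwise aligned with [align_sequences()].
#' @param constraints A [primer_constraints()] list.
#' @return A `primer_design` object (list with `pairs`, `forward`,
#'   `reverse`, `profile`, `alignment`, `constraints`).
#' @export
design_primers <- function(records, constraints = primer_constraints()) {
  records <- as_records(records)
  is_aln <- length(unique(nchar(records$seq))) == 1L &&
    any(grepl("-", records$seq, fixed = TRUE))
  aln <- if (is_aln) validate_alignment(records) else align_sequences(records)
  profile <- conservation_profile(aln, f_min = constraints$f_min)
  fwd <- enumerate_candidates(profile, aln, constraints, "forward")
  rev_ <- enumerate_candidates(profile, aln, constraints, "reverse")
  pairs <- pair_primers(fwd, rev_, constraints)
  structure(
    list(pairs = pairs, forward = fwd, reverse = rev_, profile = profile,
         alignment = aln, constraints = constraints),
    class = "primer_design"
  )
}

#' Write a primer-design report as TSV
#'
#' One row per ranked pair with windows, sequences, degeneracies, Tm and
#' the observed amplicon-length range.
#'
#' @param design A `primer_design` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(design, path) {
  stopifnot(inherits(design, "primer_design"))
  out <- design$pairs
  out$per_target <- NULL
  readr::write_tsv(out, path)
  invisible(path)
}
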