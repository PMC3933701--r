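# In-silico PCR: locate degenerate-primer binding sites on both strands of
# ungapped records, predict the products between compatible site pairs, and
# run target/non-target specificity screens. Matching follows the subset
# rule of base_match(): an ambiguous target base only counts as matched when
# the primer base covers every concretization. Acceptance requires a perfect
# 3'-terminal anchor run and a bounded mismatch count outside it. All
# coordinates are 1-based inclusive on the plus strand.

# Best/accepted windows of one primer orientation over one encoded subject.
# For a '+' hit the primer 3' end is the window's right edge; for a '-' hit
# (the plus-strand image of the primer bound to the minus strand) it is the
# left edge.
scan_one <- function(primer_enc, subject_enc, strand) {
  if (strand == "+") {
    scan_windows_cpp(primer_enc, subject_enc, FALSE)
  } else {
    rc <- rev(bitwOr(
      bitwOr(ifelse(bitwAnd(primer_enc, 1L) > 0L, 8L, 0L),
             ifelse(bitwAnd(primer_enc, 8L) > 0L, 1L, 0L)),
      bitwOr(ifelse(bitwAnd(primer_enc, 2L) > 0L, 4L, 0L),
             ifelse(bitwAnd(primer_enc, 4L) > 0L, 2L, 0L))
    ))
    scan_windows_cpp(rc, subject_enc, TRUE)
  }
}

#' Find degenerate-primer binding sites
#'
#' Every plus-strand window of each record is compared against the primer
#' (`+` sites) and against its reverse complement (`-` sites: the primer
#' bound to the minus strand, 3' end pointing left on the plus strand).
#' Sites are accepted when the perfect 3' anchor run reaches `anchor_len`
#' and the mismatch count does not exceed `max_mismatch`; accepted
#' mismatches therefore all lie 5' of the anchor.
#'
#' @param primer Degenerate primer sequence (5'->3'), or a one-row tibble
#'   with a `sequence` column.
#' @param records Tibble of ungapped subject records (`id`, `seq`), or a
#'   named character vector.
#' @param constraints A [primer_constraints()] list (anchor length and
#'   mismatch budget are taken from it).
#' @return Tibble with columns `id`, `strand`, `start`, `end`,
#'   `n_mismatch`, `anchor_run`, `mismatch_positions` (list column,
#'   primer-relative, 1 = 5' end), sorted by record then position. Records
#'   shorter than the primer yield no rows.
#' @export
find_binding_sites <- function(primer, records, constraints = primer_constraints()) {
  primer <- primer_string(primer)
  records <- as_records(records)
  pe <- encode_seq(primer, what = "primer")
  L <- length(pe)
  out <- lapply(seq_len(nrow(records)), function(k) {
    se <- encode_seq(degap(records$seq[k]),
                     what = paste0("record '", records$id[k], "'"))
    if (length(se) < L) return(NULL)
    per_strand <- lapply(c("+", "-"), function(str) {
      w <- scan_one(pe, se, str)
      acc <- w[, 2] <= constraints$max_mismatch &
        w[, 3] >= constraints$anchor_len
      if (!any(acc)) return(NULL)
      w <- w[acc, , drop = FALSE]
      tibble(
        id = records$id[k], strand = str,
        start = w[, 1], end = w[, 1] + L - 1L,
        n_mismatch = w[, 2], anchor_run = w[, 3],
        mismatch_positions = lapply(seq_len(nrow(w)), function(r) {
          mismatch_pos(pe, se, w[r, 1], str)
        })
      )
    })
    dplyr::bind_rows(per_strand)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(id = character(), strand = character(), start = integer(),
                  end = integer(), n_mismatch = integer(),
                  anchor_run = integer(), mismatch_positions = list()))
  }
  dplyr::arrange(out, match(.data$id, records$id), .data$start, .data$strand)
}

# primer-relative (1 = 5' end) mismatch positions for a window
mismatch_pos <- function(primer_enc, subject_enc, start, strand) {
  L <- length(primer_enc)
  win <- subject_enc[start:(start + L - 1L)]
  if (strand == "+") {
    which(bitwAnd(win, bitwNot(primer_enc)) != 0L)
  } else {
    # window holds the reverse complement of the primer; primer position 1
    # (5') maps to the window's right edge
    rc <- rev(bitwOr(
      bitwOr(ifelse(bitwAnd(primer_enc, 1L) > 0L, 8L, 0L),
             ifelse(bitwAnd(primer_enc, 8L) > 0L, 1L, 0L)),
      bitwOr(ifelse(bitwAnd(primer_enc, 2L) > 0L, 4L, 0L),
             ifelse(bitwAnd(primer_enc, 4L) > 0L, 2L, 0L))
    ))
    L + 1L - which(bitwAnd(win, bitwNot(rc)) != 0L)
  }
}

primer_string <- function(primer) {
  if (is.data.frame(primer)) {
    stopifnot("sequence" %in% names(primer), nrow(primer) == 1L)
    return(primer$sequence)
  }
  stopifnot(is.character(primer), length(primer) == 1L)
  toupper(primer)
}

#' Predict PCR amplicons
#'
#' Pairs every accepted forward-primer `+` site with every downstream
#' reverse-primer `-` site (and, symmetrically, reverse `+` with forward
#' `-` for products in the opposite orientation), deduplicated by
#' plus-strand interval. The product spans both primer footprints:
#' `length = rev_end - fwd_start + 1`.
#'
#' @param forward,reverse Degenerate primer sequences (5'->3').
#' @param records Tibble of ungapped subject records.
#' @param constraints A [primer_constraints()] list.
#' @param size_window Optional `c(min, max)` product-size filter in bp;
#'   `NULL` (default) keeps any size.
#' @return Tibble with columns `id`, `start`, `end`, `length`,
#'   `fwd_start`, `rev_start`, `fwd_mismatch`, `rev_mismatch`,
#'   `orientation`, sorted by record, position, length.
#' @export
predict_amplicons <- function(forward, reverse, records,
                              constraints = primer_constraints(),
                              size_window = NULL) {
  records <- as_records(records)
  fwd <- find_binding_sites(forward, records, constraints)
  rev_ <- find_binding_sites(reverse, records, constraints)
  # left/right are the upstream and downstream site tables on the plus
  # strand; for orientation "-" the downstream site is the forward primer's.
  pair_up <- function(left, right, orientation) {
    if (nrow(left) == 0L || nrow(right) == 0L) return(NULL)
    cand <- dplyr::inner_join(
      dplyr::rename(left, left_start = "start", left_end = "end",
                    left_mismatch = "n_mismatch"),
      dplyr::rename(right, right_start = "start", right_end = "end",
                    right_mismatch = "n_mismatch"),
      by = "id", relationship = "many-to-many"
    )
    cand <- cand[cand$right_start >= cand$left_end + 1L, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    fwd_left <- orientation == "+"
    tibble(
      id = cand$id, start = cand$left_start, end = cand$right_end,
      length = cand$right_end - cand$left_start + 1L,
      fwd_start = if (fwd_left) cand$left_start else cand$right_start,
      rev_start = if (fwd_left) cand$right_start else cand$left_start,
      fwd_mismatch = if (fwd_left) cand$left_mismatch else cand$right_mismatch,
      rev_mismatch = if (fwd_left) cand$right_mismatch else cand$left_mismatch,
      orientation = orientation
    )
  }
  amp <- dplyr::bind_rows(
    pair_up(fwd[fwd$strand == "+", ], rev_[rev_$strand == "-", ], "+"),
    pair_up(rev_[rev_$strand == "+", ], fwd[fwd$strand == "-", ], "-")
  )
  if (is.null(amp) || nrow(amp) == 0L) {
    return(tibble(id = character(), start = integer(), end = integer(),
                  length = integer(), fwd_start = integer(),
                  rev_start = integer(), fwd_mismatch = integer(),
                  rev_mismatch = integer(), orientation = character()))
  }
  amp <- dplyr::distinct(amp, .data$id, .data$start, .data$end,
                         .keep_all = TRUE)
  if (!is.null(size_window)) {
    amp <- amp[amp$length >= size_window[1] & amp$length <= size_window[2], ,
               drop = FALSE]
  }
  dplyr::arrange(amp, match(.data$id, records$id), .data$start, .data$length)
}

#' Extract predicted amplicon sequences
#'
#' @param amplicons Output of [predict_amplicons()].
#' @param records The subject records the amplicons were predicted on.
#' @return Tibble of records (`id`, `seq`), one per amplicon, named
#'   `<record id>|<start>-<end>`.
#' @export
amplicon_sequences <- function(amplicons, records) {
  records <- as_records(records)
  seqs <- vapply(seq_len(nrow(amplicons)), function(k) {
    s <- degap(records$seq[records$id == amplicons$id[k]][1])
    substr(s, amplicons$start[k], amplicons$end[k])
  }, character(1))
  grp <- if ("group" %in% names(records)) {
    records$group[match(amplicons$id, records$id)]
  } else NA_character_
  new_records(
    id = sprintf("%s|%d-%d", amplicons$id, amplicons$start, amplicons$end),
    description = "", group = grp, seq = seqs
  )
}

#' Target/non-target specificity screen
#'
#' Runs [predict_amplicons()] over a reference panel and summarises which
#' records amplify. A record counts as amplified when it yields at least
#' one product of any size (size filtering is opt-in via `size_window`: on
#' a gel, any band would be seen). The screen is "fully specific" when
#' every target amplifies and no non-target does.
#'
#' @param forward,reverse Degenerate primer sequences (5'->3').
#' @param targets Tibble of target records (group labels respected if
#'   present).
#' @param nontargets Tibble of non-target records (may have zero rows).
#' @param constraints A [primer_constraints()] list.
#' @param size_window Optional `c(min, max)` product-size filter.
#' @return A `specificity_report` object: per-record tibble (`id`, `panel`,
#'   `group`, `amplified`, `n_amplicons`, `min_length`, `max_length`) with
#'   summary counts, the amplicon table and the fully-specific flag as
#'   attributes.
#' @export
specificity_screen <- function(forward, reverse, targets, nontargets = NULL,
                               constraints = primer_constraints(),
                               size_window = NULL) {
  targets <- as_records(targets)
  nontargets <- if (is.null(nontargets)) {
    new_records(character(), character(), character(), character())[0, ]
  } else {
    as_records(nontargets)
  }
  if (nrow(targets) + nrow(nontargets) == 0L) {
    stop("empty panel", call. = FALSE)
  }
  if (anyDuplicated(c(targets$id, nontargets$id))) {
    stop("id collision across targets and nontargets", call. = FALSE)
  }
  panel <- dplyr::bind_rows(
    dplyr::mutate(targets, panel = "target"),
    dplyr::mutate(nontargets, panel = "nontarget")
  )
  amp <- predict_amplicons(forward, reverse, panel, constraints, size_window)
  per <- dplyr::left_join(
    panel[, c("id", "panel", if ("group" %in% names(panel)) "group")],
    dplyr::summarise(dplyr::group_by(amp, .data$id),
                     n_amplicons = dplyr::n(),
                     min_length = min(.data$length),
                     max_length = max(.data$length)),
    by = "id"
  )
  per$n_amplicons[is.na(per$n_amplicons)] <- 0L
  per$amplified <- per$n_amplicons > 0L
  per <- dplyr::relocate(per, "amplified", .after = "panel")
  summary <- tibble(
    n_targets = nrow(targets),
    targets_amplified = sum(per$amplified[per$panel == "target"]),
    n_nontargets = nrow(nontargets),
    nontargets_amplified = sum(per$amplified[per$panel == "nontarget"]),
    min_target_length = if (any(per$panel == "target" & per$amplified))
      min(per$min_length[per$panel == "target"], na.rm = TRUE) else NA_integer_,
    max_target_length = if (any(per$panel == "target" & per$amplified))
      max(per$max_length[per$panel == "target"], na.rm = TRUE) else NA_integer_
  )
  fully <- summary$targets_amplified == summary$n_targets &&
    summary$nontargets_amplified == 0L
  structure(per,
            class = c("specificity_report", class(per)),
            summary = summary, amplicons = amp, fully_specific = fully,
            size_window = size_window)
}

#' Is a specificity report fully specific?
#' @param report A `specificity_report`.
#' @return `TRUE` iff all targets and zero non-targets amplified.
#' @export
fully_specific <- function(report) {
  stopifnot(inherits(report, "specificity_report"))
  attr(report, "fully_specific")
}

#' In-silico validation report for a reference panel with a primer system
#'
#' Convenience wrapper reproducing the design-time validation protocol on
#' user-supplied reference sequences (e.g. the oriV/rep replicon references
#' fetched by accession): per-target best binding sites for both primers
#' (anchor run and mismatch count), predicted product lengths, and the
#' specificity summary against an optional non-target panel.
#'
#' @param targets Tibble of reference records or a FASTA path.
#' @param nontargets Optional non-target records or FASTA path.
#' @param primers Two-row primer tibble (default [incp9_primers()]).
#' @param constraints A [primer_constraints()] list.
#' @return A list with `validation` (per target and primer: anchor run,
#'   mismatches, pass), `amplicons`, `screen` (a `specificity_report`).
#' @export
incp9_reference_report <- function(targets, nontargets = NULL,
                                   primers = incp9_primers(),
                                   constraints = primer_constraints()) {
  if (is.character(targets) && length(targets) == 1L) targets <- read_fasta(targets)
  if (is.character(nontargets) && length(nontargets) == 1L) {
    nontargets <- read_fasta(nontargets)
  }
  targets <- as_records(targets)
  fwd <- primers$sequence[primers$role == "forward"][1]
  rev_ <- primers$sequence[primers$role == "reverse"][1]
  validation <- dplyr::bind_rows(
    dplyr::mutate(validate_candidate(fwd, targets, constraints, "forward"),
                  primer = "forward"),
    dplyr::mutate(validate_candidate(rev_, targets, constraints, "reverse"),
                  primer = "reverse")
  )
  screen <- specificity_screen(fwd, rev_, targets, nontargets, constraints)
  list(validation = validation,
       amplicons = attr(screen, "amplicons"),
       screen = screen)
}
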