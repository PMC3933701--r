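# Seeded generator of nine-subgroup replicon panels with planted primer
# sites, decoy non-targets and query amplicons, plus full ground truth, so
# design, in-silico PCR and classification are all testable without any
# download. Members are substitution-mutated backbones (root -> subgroup
# ancestor -> member); the primer-binding blocks are conserved: mutation at
# a planted-site position is restricted to the primer code's expansion set
# (so site diversity never leaves the degenerate cover), and the spacer
# between the sites varies in length via a centred deletion from a maximal
# root spacer, keeping members homologous and site columns gap-free in the
# true alignment.

.subgroup_labels <- paste("IncP-9",
                          c("alpha", "beta", "gamma", "delta", "epsilon",
                            "zeta", "eta", "theta", "iota"))

#' Simulation configuration for synthetic replicon panels
#'
#' Defaults emulate the IncP-9 reference structure: nine subgroups, low
#' within-subgroup and substantial between-subgroup divergence, and spacer
#' (insert) lengths of 568-595 bp so that two 21-mer primer footprints
#' yield 610-637 bp products.
#'
#' @param n_subgroups Number of subgroups (default 9).
#' @param seqs_per_subgroup Members per subgroup (default 3, giving a
#'   27-record panel comparable to a 28-reference design set).
#' @param seq_length Root backbone length in nt, spacer included
#'   (default 900).
#' @param within_divergence Substitution rate member vs subgroup ancestor
#'   (default 0.02 substitutions/site).
#' @param between_divergence Substitution rate ancestor vs root
#'   (default 0.15).
#' @param insert_length_range Per-member spacer length range between the
#'   planted sites, bp (default `c(568, 595)`).
#' @param n_nontargets Number of site-free decoy records (default 6).
#' @param anchor_protect When `TRUE` (default), mutation never damages a
#'   planted site: site positions only vary inside the primer's expansion
#'   sets. When `FALSE`, a post-planting unconstrained substitution pass at
#'   `within_divergence` covers the whole sequence, 3' anchors included.
#' @param seed Integer RNG seed recorded in all outputs (default 42).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subgroups = 9L, seqs_per_subgroup = 3L,
                       seq_length = 900L, within_divergence = 0.02,
                       between_divergence = 0.15,
                       insert_length_range = c(568L, 595L),
                       n_nontargets = 6L, anchor_protect = TRUE,
                       seed = 42L) {
  stopifnot(
    n_subgroups >= 1L, seqs_per_subgroup >= 1L,
    length(insert_length_range) == 2L,
    insert_length_range[1] >= 1L,
    insert_length_range[2] >= insert_length_range[1],
    n_nontargets >= 0L
  )
  if (within_divergence < 0 || between_divergence < within_divergence ||
      between_divergence >= 0.75) {
    stop("divergences must satisfy 0 <= within <= between < 0.75",
         call. = FALSE)
  }
  structure(list(
    n_subgroups = as.integer(n_subgroups),
    seqs_per_subgroup = as.integer(seqs_per_subgroup),
    seq_length = as.integer(seq_length),
    within_divergence = within_divergence,
    between_divergence = between_divergence,
    insert_length_range = as.integer(insert_length_range),
    n_nontargets = as.integer(n_nontargets),
    anchor_protect = isTRUE(anchor_protect),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# per-position allowed-base sets: list of character vectors (length-1 sets
# are immutable); substitute at `rate` per position, uniformly among the
# other allowed bases
mutate_chars <- function(chars, rate, allowed = NULL) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    opts <- if (is.null(allowed)) c("A", "C", "G", "T") else allowed[[i]]
    opts <- setdiff(opts, chars[i])
    if (length(opts)) chars[i] <- sample(opts, 1L)
  }
  chars
}

#' Simulate a nine-subgroup replicon panel with planted primer sites
#'
#' Builds a random root carrying the primer pair's footprints around a
#' maximal spacer, evolves subgroup ancestors and members by substitution,
#' varies each member's spacer length by a centred deletion, and adds
#' site-free random decoys. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()] list.
#' @param primers Two-row primer tibble (`sequence`, `role`); default the
#'   published IncP-9 pair ([incp9_primers()]).
#' @return A `replicon_panel` list: `targets` and `nontargets` record
#'   tibbles, `truth` (per member: planted coordinates, insert and
#'   expected amplicon length), `primers`, `config`.
#' @export
simulate_panel <- function(config = sim_config(), primers = incp9_primers()) {
  stopifnot(inherits(config, "sim_config"))
  fwd <- primers$sequence[primers$role == "forward"][1]
  rev_ <- primers$sequence[primers$role == "reverse"][1]
  Lf <- nchar(fwd); Lr <- nchar(rev_)
  ins_max <- config$insert_length_range[2]
  arch <- Lf + ins_max + Lr
  # keep a homologous flank on both sides: a site flush against a sequence
  # end makes terminal alignment columns ambiguous
  flank <- 30L
  if (config$seq_length < arch + 2L * flank) {
    stop(sprintf(
      "seq_length (%d) too short to host sites + insert + %d nt flanks (%d)",
      config$seq_length, flank, arch + 2L * flank), call. = FALSE)
  }
  expand_sets <- function(p) {
    m <- encode_seq(p, what = "primer")
    lapply(m, function(b) c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L])
  }
  fwd_sets <- expand_sets(fwd)
  rev_site_sets <- expand_sets(reverse_complement(rev_))  # plus-strand image

  withr::with_seed(config$seed, {
    Ltot <- config$seq_length
    fwd_start <- flank + sample.int(Ltot - arch - 2L * flank + 1L, 1L)
    fwd_end <- fwd_start + Lf - 1L
    ins_cols <- (fwd_end + 1L):(fwd_end + ins_max)
    rev_cols <- (fwd_end + ins_max + 1L):(fwd_end + ins_max + Lr)

    root <- sample(c("A", "C", "G", "T"), Ltot, replace = TRUE)
    root[fwd_start:fwd_end] <- vapply(fwd_sets, function(s) sample(s, 1L)[1],
                                      character(1))
    root[rev_cols] <- vapply(rev_site_sets, function(s) sample(s, 1L)[1],
                             character(1))

    # allowed-base map: site positions locked to the primer expansion sets
    allowed <- vector("list", Ltot)
    allowed[fwd_start:fwd_end] <- fwd_sets
    allowed[rev_cols] <- rev_site_sets
    allowed[vapply(allowed, is.null, logical(1))] <-
      list(c("A", "C", "G", "T"))

    labels <- if (config$n_subgroups <= length(.subgroup_labels)) {
      .subgroup_labels[seq_len(config$n_subgroups)]
    } else {
      paste("subgroup", seq_len(config$n_subgroups))
    }
    short <- gsub("^IncP-9 ", "", labels)

    targets <- list(); truth <- list()
    for (g in seq_len(config$n_subgroups)) {
      anc <- mutate_chars(root, config$between_divergence, allowed)
      for (k in seq_len(config$seqs_per_subgroup)) {
        mem <- mutate_chars(anc, config$within_divergence, allowed)
        ins_range <- seq(config$insert_length_range[1],
                         config$insert_length_range[2])
        ins_len <- ins_range[sample.int(length(ins_range), 1L)]
        n_del <- ins_max - ins_len
        keep_head <- ceiling(ins_len / 2)
        keep <- c(ins_cols[seq_len(keep_head)],
                  if (ins_len > keep_head)
                    ins_cols[(ins_max - (ins_len - keep_head) + 1L):ins_max])
        seq_chars <- c(mem[1:fwd_end], mem[keep], mem[rev_cols],
                       if (rev_cols[Lr] < Ltot) mem[(rev_cols[Lr] + 1L):Ltot])
        if (!config$anchor_protect) {
          seq_chars <- mutate_chars(seq_chars, config$within_divergence)
        }
        id <- sprintf("%s_%02d", short[g], k)
        targets[[length(targets) + 1L]] <-
          new_records(id, "synthetic replicon", labels[g],
                      paste(seq_chars, collapse = ""))
        truth[[length(truth) + 1L]] <- tibble(
          id = id, group = labels[g],
          fwd_start = fwd_start, fwd_end = fwd_end,
          rev_start = fwd_end + ins_len + 1L,
          rev_end = fwd_end + ins_len + Lr,
          insert_length = ins_len,
          amplicon_length = ins_len + Lf + Lr
        )
      }
    }
    nontargets <- lapply(seq_len(config$n_nontargets), function(k) {
      new_records(sprintf("decoy_%02d", k), "synthetic non-target plasmid",
                  NA_character_,
                  paste(sample(c("A", "C", "G", "T"), Ltot, replace = TRUE),
                        collapse = ""))
    })
    structure(list(
      targets = dplyr::bind_rows(targets),
      nontargets = if (length(nontargets)) dplyr::bind_rows(nontargets) else
        new_records(character(), character(), character(), character())[0, ],
      truth = dplyr::bind_rows(truth),
      primers = primers,
      config = config
    ), class = "replicon_panel")
  })
}

#' Simulate query amplicons from a synthetic panel
#'
#' Emulates a clone library: per subgroup, `n_per_subgroup` queries are cut
#' from members' planted amplicon intervals (both primer footprints
#' included) and diverged by unconstrained substitution.
#'
#' @param panel A `replicon_panel` from [simulate_panel()].
#' @param n_per_subgroup Queries per subgroup (0 gives an empty result).
#' @param divergence Per-site substitution rate applied to each query
#'   (must be < 0.75).
#' @param seed Integer RNG seed (default: panel seed + 1).
#' @return Tibble of query records (`id`, `group` = generating subgroup,
#'   `seq`).
#' @export
simulate_queries <- function(panel, n_per_subgroup = 2L, divergence = 0.02,
                             seed = NULL) {
  stopifnot(inherits(panel, "replicon_panel"))
  if (divergence >= 0.75) stop("divergence must be < 0.75", call. = FALSE)
  if (n_per_subgroup < 1L) {
    return(new_records(character(), character(), character(), character())[0, ])
  }
  if (is.null(seed)) seed <- panel$config$seed + 1L
  truth <- panel$truth
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (g in unique(truth$group)) {
      members <- truth[truth$group == g, ]
      for (k in seq_len(n_per_subgroup)) {
        m <- members[((k - 1L) %% nrow(members)) + 1L, ]
        s <- panel$targets$seq[panel$targets$id == m$id]
        amp <- strsplit(substr(s, m$fwd_start, m$rev_end), "")[[1]]
        amp <- mutate_chars(amp, divergence)
        rows[[length(rows) + 1L]] <- new_records(
          sprintf("clone_%s_%02d", gsub("^IncP-9 ", "", g), k),
          sprintf("synthetic clone from %s", m$id), g,
          paste(amp, collapse = "")
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Write a synthetic panel to disk
#'
#' Targets, non-targets (FASTA with `group=` headers) and the truth table
#' (TSV), plus the planted primer registry.
#'
#' @param panel A `replicon_panel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "replicon_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(panel$targets, file.path(dir, "targets.fasta"))
  write_fasta(panel$nontargets, file.path(dir, "nontargets.fasta"))
  readr::write_tsv(panel$truth, file.path(dir, "truth.tsv"))
  reg <- panel$primers
  write.dcf(as.data.frame(reg), file.path(dir, "primers.registry"))
  invisible(dir)
}
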