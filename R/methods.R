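# broom-style accessors and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.primer_design <- function(x, ...) {
  cat("<primer_design>\n")
  cat(sprintf("  alignment: %d rows x %d columns\n",
              nrow(x$alignment), alignment_width(x$alignment)))
  cat(sprintf("  candidates: %d forward, %d reverse; %d valid pairs\n",
              nrow(x$forward), nrow(x$reverse), nrow(x$pairs)))
  if (nrow(x$pairs)) {
    p <- x$pairs[1, ]
    cat(sprintf("  best pair: F %s (cols %d-%d) / R %s (cols %d-%d)\n",
                p$fwd_sequence, p$fwd_window_start, p$fwd_window_end,
                p$rev_sequence, p$rev_window_start, p$rev_window_end))
    cat(sprintf("  amplicons: %d-%d bp across %d targets\n",
                p$amplicon_min_obs, p$amplicon_max_obs,
                nrow(p$per_target[[1]])))
  }
  invisible(x)
}

#' @rdname design_primers
#' @param x A `primer_design` object.
#' @param ... Unused.
#' @method tidy primer_design
#' @export
tidy.primer_design <- function(x, ...) {
  out <- x$pairs
  out$per_target <- NULL
  out
}

#' @rdname design_primers
#' @method glance primer_design
#' @export
glance.primer_design <- function(x, ...) {
  tibble(
    n_forward = nrow(x$forward), n_reverse = nrow(x$reverse),
    n_pairs = nrow(x$pairs),
    best_degeneracy = if (nrow(x$pairs)) x$pairs$max_degeneracy[1] else NA_integer_,
    best_amplicon_min = if (nrow(x$pairs)) x$pairs$amplicon_min_obs[1] else NA_integer_,
    best_amplicon_max = if (nrow(x$pairs)) x$pairs$amplicon_max_obs[1] else NA_integer_
  )
}

#' @rdname design_primers
#' @param object A `primer_design` object.
#' @method autoplot primer_design
#' @export
autoplot.primer_design <- function(object, ...) {
  prof <- object$profile
  n <- nrow(object$alignment)
  prof$conservation <- pmax(prof$n_A, prof$n_C, prof$n_G, prof$n_T) /
    pmax(n * (1 - prof$gap_fraction), 1e-9)
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$column,
                                          y = .data$conservation)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "alignment column", y = "majority-base frequency",
                  title = "Conservation profile and selected primer windows") +
    ggplot2::theme_minimal()
  if (nrow(object$pairs)) {
    best <- object$pairs[1, ]
    wins <- tibble(
      xmin = c(best$fwd_window_start, best$rev_window_start),
      xmax = c(best$fwd_window_end, best$rev_window_end),
      role = c("forward", "reverse")
    )
    p <- p + ggplot2::geom_rect(
      data = wins, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$role),
      alpha = 0.25
    )
  }
  p
}

#' @export
print.specificity_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<specificity_report>\n")
  cat(sprintf("  targets amplified: %d/%d; non-targets amplified: %d/%d\n",
              s$targets_amplified, s$n_targets,
              s$nontargets_amplified, s$n_nontargets))
  if (!is.na(s$min_target_length)) {
    cat(sprintf("  target product lengths: %d-%d bp\n",
                s$min_target_length, s$max_target_length))
  }
  cat(sprintf("  fully specific: %s\n", attr(x, "fully_specific")))
  invisible(x)
}

#' @rdname specificity_screen
#' @param x A `specificity_report`.
#' @param ... Unused.
#' @method tidy specificity_report
#' @export
tidy.specificity_report <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname specificity_screen
#' @method glance specificity_report
#' @export
glance.specificity_report <- function(x, ...) {
  dplyr::mutate(attr(x, "summary"), fully_specific = attr(x, "fully_specific"))
}

#' @rdname specificity_screen
#' @param object A `specificity_report`.
#' @method autoplot specificity_report
#' @export
autoplot.specificity_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$panel, fill = .data$amplified)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = NULL, y = "records",
                  title = "In-silico PCR specificity screen") +
    ggplot2::theme_minimal()
}

#' @rdname classify_amplicons
#' @param x A `subgroup_classification`.
#' @param ... Unused.
#' @method tidy subgroup_classification
#' @export
tidy.subgroup_classification <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname classify_amplicons
#' @method glance subgroup_classification
#' @export
glance.subgroup_classification <- function(x, ...) {
  tibble(
    n_queries = nrow(x),
    n_unaffiliated = sum(x$label == "unaffiliated"),
    n_labels = length(unique(x$label[x$label != "unaffiliated"])),
    mean_distance = mean(x$distance),
    mean_support = mean(x$support),
    tau = attr(x, "tau"), n_reps = attr(x, "n_reps"), seed = attr(x, "seed")
  )
}

#' @rdname classify_amplicons
#' @param object A `subgroup_classification`.
#' @method autoplot subgroup_classification
#' @export
autoplot.subgroup_classification <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance, y = .data$support,
                                  colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "tau"), linetype = 2) +
    ggplot2::labs(x = "distance to nearest reference (subst/site)",
                  y = "bootstrap support (%)",
                  title = "Amplicon subgroup assignments") +
    ggplot2::theme_minimal()
}

#' @export
print.replicon_panel <- function(x, ...) {
  cat("<replicon_panel>\n")
  cat(sprintf("  %d targets in %d subgroups; %d non-targets; seed %d\n",
              nrow(x$targets), length(unique(x$truth$group)),
              nrow(x$nontargets), x$config$seed))
  cat(sprintf("  expected amplicons: %d-%d bp\n",
              min(x$truth$amplicon_length), max(x$truth$amplicon_length)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' @importFrom utils str
NULL
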