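#' Figure-style summaries of an annotated repertoire
#'
#' Small ggplot2 wrappers over the summary tables: percent of sequences
#' with at least one CDR mutation per sample, stacked isotype
#' distributions, and mean mutation counts per region class with
#' standard errors.
#'
#' @param annot Annotation tibble from [annotate_repertoire()].
#' @return A ggplot object.
#' @name repertoire-plots
NULL

sample_label <- function(d) {
  paste(dplyr::coalesce(d$compartment, "?"),
        dplyr::coalesce(d$population, "?"))
}

#' @rdname repertoire-plots
#' @export
plot_percent_mutated <- function(annot) {
  s <- repertoire_summary(annot)
  s$sample <- sample_label(s)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$sample,
                                  y = .data$pct_mutated_cdr)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_seq), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "% sequences with CDR mutation") +
    ggplot2::ylim(0, 105) +
    ggplot2::theme_classic()
}

#' @rdname repertoire-plots
#' @export
plot_isotype_distribution <- function(annot) {
  d <- annot
  d$sample <- sample_label(d)
  d <- dplyr::count(d, .data$sample, .data$isotype)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$n,
                                  fill = .data$isotype)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "fraction of sequences", fill = NULL) +
    ggplot2::theme_classic()
}

#' @rdname repertoire-plots
#' @export
plot_mutation_counts <- function(annot) {
  d <- annot
  d$sample <- sample_label(d)
  long <- tidyr::pivot_longer(d[, c("sample", "mut_cdr", "mut_fr")],
                              c("mut_cdr", "mut_fr"),
                              names_to = "region_class",
                              values_to = "n_mut")
  long$region_class <- ifelse(long$region_class == "mut_cdr", "CDR", "FR")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  agg <- long |>
    dplyr::group_by(.data$sample, .data$region_class) |>
    dplyr::summarise(mean = mean(.data$n_mut), sem = sem(.data$n_mut),
                     .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$sample, y = .data$mean,
                                    fill = .data$region_class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "nucleotide mutations per sequence",
                  fill = NULL) +
    ggplot2::theme_classic()
}

#' Plot per-level clone counts by compartment membership
#'
#' @param level_hist Output of [tree_level_histogram()].
#' @return A ggplot object.
#' @export
plot_tree_levels <- function(level_hist) {
  ggplot2::ggplot(level_hist, ggplot2::aes(x = .data$level, y = .data$n,
                                           fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(shared = "grey60",
                                          `ln-only` = "#3366aa",
                                          `lung-only` = "#cc3333"),
                               na.value = "grey85") +
    ggplot2::labs(x = "tree level (0 = germline)", y = "clones",
                  fill = NULL) +
    ggplot2::theme_classic()
}

#' Plot UMI-weighted clonal space of the top clones
#'
#' @param clones Clone tibble from [define_clones()].
#' @param top_n Number of clones shown individually.
#' @return A ggplot object (stacked clonal-space bar).
#' @export
plot_clonal_space <- function(clones, top_n = 25) {
  cs <- clonal_space(clones, top_n)
  d <- cs$top_fractions
  d$clone_id <- factor(d$clone_id, levels = rev(d$clone_id))
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$fraction,
                                  fill = .data$clone_id)) +
    ggplot2::geom_col(colour = "white", linewidth = 0.2,
                      show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of clonal space") +
    ggplot2::theme_classic()
}

#' Plot an amino-acid substitution profile
#'
#' @param logo Output of [substitution_logo()].
#' @return A ggplot object (residue letters scaled by frequency).
#' @export
plot_substitution_logo <- function(logo) {
  ggplot2::ggplot(logo, ggplot2::aes(x = factor(.data$aa_pos),
                                     y = .data$freq,
                                     fill = .data$read_aa,
                                     label = .data$read_aa)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2,
                      show.legend = FALSE) +
    ggplot2::geom_text(position = ggplot2::position_stack(vjust = 0.5),
                       size = 2.5) +
    ggplot2::labs(x = "amino-acid position",
                  y = "substitution frequency") +
    ggplot2::theme_classic()
}

#' @export
autoplot.sim_result <- function(object, ...) {
  sizes <- object$clone_sizes
  d <- tibble::tibble(
    time = rep(object$timeline$time, ncol(sizes)),
    clone = factor(rep(seq_len(ncol(sizes)), each = nrow(sizes))),
    size = as.vector(sizes)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$size,
                                  colour = .data$clone)) +
    ggplot2::geom_line(show.legend = FALSE, alpha = 0.8) +
    ggplot2::labs(x = "time (days)", y = "clone size (cells)",
                  title = object$config$scenario) +
    ggplot2::theme_classic()
}

#' @export
autoplot.sim_ensemble <- function(object, ...) {
  tl <- object$timeline
  long <- tidyr::pivot_longer(
    tl, -"time",
    names_to = c("stat", ".value"), names_pattern = "(.*)_(mean|sem)$"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL,
                  title = paste(object$config$scenario, "ensemble,",
                                object$n_runs, "runs")) +
    ggplot2::theme_classic()
}
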