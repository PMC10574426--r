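#' Heat map of a docking affinity matrix
#'
#' Ligand-by-receptor tiles filled by best affinity; more negative (more
#' favorable) cells are darker.
#'
#' @param object An [best_pose()] `affinity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.affinity_matrix <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$receptor, y = .data$ligand,
                               fill = .data$affinity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#08306b", high = "#fee0d2",
                                 name = "affinity\n(kcal/mol)") +
    ggplot2::labs(x = "receptor", y = "ligand") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dot plot of enrichment results
#'
#' Terms against gene ratio, sized by count and colored by adjusted
#' p-value, faceted by category — the conventional presentation of
#' over-representation results.
#'
#' @param object A [run_ora()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.herb_ora <- function(object, ...) {
  df <- as_tibble(object)
  df$term_name <- factor(df$term_name,
                         levels = rev(unique(df$term_name)))
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$gene_ratio, y = .data$term_name,
                               size = .data$count, color = .data$p_adjust)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient(low = "#d7301f", high = "#2b8cbe",
                                  name = "p.adjust") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "gene ratio", y = NULL, size = "count") +
    ggplot2::theme_minimal()
}

#' Trajectory plot with stability annotation
#'
#' @param object A [trajectory_series()].
#' @param assessment Optional [assess_stability()] result; when supplied,
#'   the equilibration time is drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_series <- function(object, assessment = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(color = "#2b8cbe") +
    ggplot2::labs(x = "time (ns)", y = "value",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
  if (!is.null(assessment) && isTRUE(assessment$stable)) {
    p <- p + ggplot2::geom_vline(xintercept = assessment$equilibration_time,
                                 linetype = "dashed", color = "#d7301f")
  }
  p
}

#' Two-set Venn diagram of a target overlap
#'
#' @param overlap An [intersect_targets()] result.
#' @param labels Names of the two sets.
#' @return A ggplot object.
#' @export
plot_venn <- function(overlap, labels = c("compound targets",
                                          "disease targets")) {
  if (!inherits(overlap, "target_overlap")) {
    abort("`overlap` must come from intersect_targets()")
  }
  circles <- tibble(
    x = c(-0.6, 0.6), y = c(0, 0), set = labels
  )
  counts <- tibble(
    x = c(-1.1, 0, 1.1), y = c(0, 0, 0),
    n = unname(overlap$venn[c("a_only", "common", "b_only")])
  )
  angle <- seq(0, 2 * pi, length.out = 200)
  rings <- bind_rows(map(seq_len(2), function(i) {
    tibble(x = circles$x[i] + cos(angle), y = sin(angle), set = circles$set[i])
  }))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = rings,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    color = .data$set)) +
    ggplot2::geom_text(data = counts,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$n), size = 6) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(color = NULL)
}
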