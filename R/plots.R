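#' Point and cluster map figure
#'
#' The classic concept-mapping figure: every statement is a labeled point
#' in the 2-D configuration, with statements of a cluster enclosed by the
#' cluster's convex hull. Hulls degenerate to segments or points for tiny
#' clusters without error.
#'
#' @param point_map `cm_pointmap`.
#' @param solution optional `cm_solution` for hulls and coloring.
#' @param labels optional [suggest_labels()] output; top candidates become
#'   hull annotations.
#' @return a ggplot object.
#' @export
plot_point_map <- function(point_map, solution = NULL, labels = NULL) {
  df <- data.frame(statement_id = rownames(point_map$coordinates),
                   x = point_map$coordinates[, 1],
                   y = point_map$coordinates[, 2])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(solution)) {
    df$cluster <- factor(solution$assignment[df$statement_id])
    hulls <- do.call(rbind, lapply(split(df, df$cluster), function(d) {
      d[chull(d$x, d$y), , drop = FALSE]
    }))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$cluster)) +
      ggplot2::geom_polygon(data = hulls,
                            ggplot2::aes(fill = .data$cluster),
                            alpha = 0.15, show.legend = FALSE)
    if (!is.null(labels)) {
      cent <- do.call(rbind, lapply(split(df, df$cluster), function(d) {
        lab <- labels[[as.character(d$cluster[1])]]
        data.frame(x = mean(d$x), y = mean(d$y), cluster = d$cluster[1],
                   label = if (!is.null(lab) && nrow(lab)) lab$label[1] else "")
      }))
      p <- p + ggplot2::geom_text(data = cent,
                                  ggplot2::aes(label = .data$label),
                                  fontface = "bold", show.legend = FALSE)
    }
  }
  p + ggplot2::geom_text(ggplot2::aes(label = .data$statement_id),
                         size = 3, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  caption = sprintf("stress-1 = %.4f", point_map$stress)) +
    ggplot2::theme_minimal()
}

#' Pattern-match ladder figure
#'
#' Two vertical 1-5 importance axes, one per rater group, with a line per
#' cluster connecting its two group means; crossing lines reveal rank
#' disagreements between the groups.
#'
#' @param pmatch `cm_pattern_match`.
#' @return a ggplot object.
#' @export
plot_pattern_match <- function(pmatch) {
  K <- length(pmatch$clusters)
  df <- data.frame(cluster = factor(rep(pmatch$clusters, 2)),
                   side = rep(c(1, 2), each = K),
                   mean = c(pmatch$mean_a, pmatch$mean_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$side, y = .data$mean,
                                   group = .data$cluster,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(data = df[df$side == 1, ],
                       ggplot2::aes(label = .data$cluster),
                       nudge_x = -0.06, show.legend = FALSE) +
    ggplot2::geom_text(data = df[df$side == 2, ],
                       ggplot2::aes(label = .data$cluster),
                       nudge_x = 0.06, show.legend = FALSE) +
    ggplot2::scale_x_continuous(breaks = c(1, 2),
                                labels = c(pmatch$scope_a, pmatch$scope_b),
                                limits = c(0.8, 2.2)) +
    ggplot2::scale_y_continuous(limits = c(1, 5)) +
    ggplot2::labs(x = NULL, y = "mean importance (1-5)",
                  caption = sprintf("r = %.3f", pmatch$correlation)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Write the map and pattern-match figures
#'
#' Renders the point/cluster map and (when available) the pattern-match
#' ladder as SVG — a deterministic vector format, so re-rendering the same
#' inputs yields byte-identical files.
#'
#' @param point_map `cm_pointmap`.
#' @param solution `cm_solution`.
#' @param pmatch optional `cm_pattern_match`.
#' @param output_dir directory for the figures.
#' @param labels optional label suggestions for hull annotation.
#' @return character vector of files written.
#' @export
render_maps <- function(point_map, solution, pmatch = NULL, output_dir = ".",
                        labels = NULL) {
  if (!capabilities("cairo"))
    cm_abort("SVG rendering needs cairo graphics support",
             class = "cm_computation_error")
  files <- character()
  save_svg <- function(plot, path, width = 7, height = 6) {
    svg(path, width = width, height = height)
    on.exit(dev.off())
    print(plot)
    files <<- c(files, path)
  }
  save_svg(plot_point_map(point_map, solution, labels),
           file.path(output_dir, "cluster_map.svg"))
  if (!is.null(pmatch))
    save_svg(plot_pattern_match(pmatch),
             file.path(output_dir, "pattern_match.svg"), width = 5, height = 6)
  files
}
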