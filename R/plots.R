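# ggplot2 views of the main result types.

#' @describeIn classify_dex Bar chart of up/down call counts per contrast.
#' @export
autoplot.dex_result <- function(object, ...) {
  counts <- object$table %>%
    dplyr::filter(.data$call != "ns") %>%
    dplyr::count(.data$contrast, .data$call)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = factor(.data$contrast), y = .data$n,
                               fill = .data$call)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "#d73027",
                                          down = "#4575b4")) +
    ggplot2::labs(x = "time point (DIV) vs baseline",
                  y = "genes called", fill = NULL,
                  title = sprintf("Differential expression (FDR < %g)",
                                  object$q_cut)) +
    ggplot2::theme_minimal()
}

#' @describeIn select_dynamic_genes Cluster mean log2-FC trajectories
#'   (after clustering) or the DTW distance distribution with the
#'   threshold.
#' @param object a `dtw_result`.
#' @export
autoplot.dtw_result <- function(object, ...) {
  if (!is.null(object$cluster_means)) {
    df <- tibble::as_tibble(object$cluster_means, rownames = "cluster") %>%
      tidyr::pivot_longer(-"cluster", names_to = "div",
                          values_to = "log2fc") %>%
      dplyr::mutate(div = as.numeric(.data$div))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$div, y = .data$log2fc,
                                     color = .data$cluster)) +
      ggplot2::geom_line(linewidth = 1) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "days in vitro", y = "mean log2 FC vs baseline",
                    title = "Trajectory cluster means") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$table, ggplot2::aes(x = .data$dtw_dist)) +
      ggplot2::geom_histogram(bins = 50, fill = "grey60") +
      ggplot2::geom_vline(xintercept = object$noise_model$tau,
                          linetype = 2, color = "#d73027") +
      ggplot2::labs(x = "DTW distance to flat reference", y = "genes",
                    title = sprintf("Dynamic threshold tau = %.3g",
                                    object$noise_model$tau)) +
      ggplot2::theme_minimal()
  }
}

#' @describeIn enrichment_grid Heat map of log odds ratios, shown only
#'   where the grid-wide FDR is below the reporting threshold, with
#'   significance marks.
#' @param object an `enrichment_grid`.
#' @param ... unused.
#' @export
autoplot.enrichment_grid <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      shown_or = ifelse(.data$reported, .data$log_or, NA))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$list,
                                   fill = .data$shown_or)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$tier), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#4575b4", mid = "white",
                                  high = "#d73027", na.value = "grey95") +
    ggplot2::labs(fill = "log OR",
                  title = "Risk-list enrichment (shown if FDR < report cut)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn rrho_map Tile map of -log10 hypergeometric overlap
#'   p-values across rank-threshold pairs.
#' @param object an `rrho_map`.
#' @export
autoplot.rrho_map <- function(object, ...) {
  df <- tibble::as_tibble(object$neglog10p, rownames = "rank_a") %>%
    tidyr::pivot_longer(-"rank_a", names_to = "rank_b",
                        values_to = "neglog10p") %>%
    dplyr::mutate(rank_a = as.numeric(.data$rank_a),
                  rank_b = as.numeric(.data$rank_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_a, y = .data$rank_b,
                                   fill = .data$neglog10p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "rank threshold, signature A",
                  y = "rank threshold, signature B",
                  fill = "-log10 p",
                  title = sprintf("RRHO map (max = %.1f)",
                                  object$max_neglog10p)) +
    ggplot2::theme_minimal()
}

#' Module eigengene trajectories
#'
#' Line plot of the per-time-point log2-FC eigengene of every module, the
#' module-level summary of regulation over the course.
#'
#' @param eigengenes result of [module_eigengene()].
#' @return A ggplot object.
#' @export
plot_module_trajectories <- function(eigengenes) {
  df <- tibble::as_tibble(eigengenes$trajectories, rownames = "div") %>%
    tidyr::pivot_longer(-"div", names_to = "module",
                        values_to = "eigengene") %>%
    dplyr::mutate(div = as.numeric(.data$div))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$div, y = .data$eigengene,
                                   color = .data$module)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "days in vitro", y = "log2-FC eigengene",
                  title = "Module eigengene trajectories") +
    ggplot2::theme_minimal()
}
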