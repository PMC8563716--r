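#' Plot ensemble categorization accuracy by stimulus type and condition
#'
#' Median of bootstrapped per-batch mean accuracies with percentile 95%
#' intervals, split by stimulus role (or exception category) and
#' condition.
#'
#' @param ensembles An `hc_ensemble` or list of ensembles (both
#'   conditions).
#' @param by `"role"` or `"category"` (the latter restricted to
#'   exceptions).
#' @param checkpoint Checkpoint to plot (default 144).
#' @param n_boot,seed Bootstrap settings for [aggregate_accuracy()].
#' @return A ggplot object.
#' @export
plot_accuracy <- function(ensembles, by = c("role", "category"),
                          checkpoint = 144L, n_boot = 2000L, seed = 1L) {
  by <- match.arg(by)
  tbl <- accuracy_table(ensembles)
  tbl <- tbl[tbl$checkpoint == checkpoint, ]
  if (by == "category") tbl <- tbl[tbl$role == "exception", ]
  agg <- aggregate_accuracy(tbl, .data[[by]], .data$condition,
                            n_boot = n_boot, seed = seed)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data[[by]], y = .data$boot_median,
                                    colour = .data$condition,
                                    shape = .data$condition)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::labs(y = "Luce-choice accuracy", x = NULL,
                  title = paste0("Model accuracy at trial ", checkpoint)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hc_ensemble <- function(object, ...) plot_accuracy(object, ...)

#' Heatmap of a representational similarity (or difference) matrix
#'
#' @param matrix 10 x 10 matrix in canonical stimulus order.
#' @param title Plot title.
#' @param limits Fill limits; defaults symmetric for difference matrices
#'   (any negative entry) and \[0,1\]-ish otherwise.
#' @return A ggplot object.
#' @export
plot_rsa <- function(matrix, title = NULL, limits = NULL) {
  df <- as.data.frame(as.table(matrix))
  names(df) <- c("row", "col", "r")
  df$row <- factor(df$row, levels = rev(rownames(matrix)))
  df$col <- factor(df$col, levels = colnames(matrix))
  if (is.null(limits)) {
    limits <- if (any(df$r < 0, na.rm = TRUE)) c(-1, 1) * max(abs(df$r), na.rm = TRUE)
              else range(df$r, na.rm = TRUE)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = mean(limits), limits = limits) +
    ggplot2::labs(x = NULL, y = NULL, title = title, fill = "r") +
    ggplot2::theme_minimal()
}

#' Plot a Procrustes-aligned Sammon trajectory
#'
#' Each stimulus's 2-D position across checkpoints, with later
#' checkpoints drawn more opaque; category A round, category B square,
#' exceptions labelled.
#'
#' @param traj An [trajectory()] tibble.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  traj <- dplyr::mutate(traj,
    category = ifelse(.data$stimulus_id %in% c("PA1", "PA2", "RA1", "RA2", "EA"),
                      "A", "B"),
    role = dplyr::case_when(
      grepl("^P", .data$stimulus_id) ~ "prototype",
      grepl("^R", .data$stimulus_id) ~ "rule_follower",
      TRUE ~ "exception"))
  last_cp <- max(traj$checkpoint)
  ggplot2::ggplot(traj, ggplot2::aes(.data$x, .data$y,
                                     colour = .data$role,
                                     shape = .data$category,
                                     alpha = .data$checkpoint,
                                     group = .data$stimulus_id)) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(data = function(d) d[d$checkpoint == last_cp, ],
                       ggplot2::aes(label = .data$stimulus_id),
                       vjust = -0.8, alpha = 1, size = 3, show.legend = FALSE) +
    ggplot2::scale_alpha_continuous(range = c(0.25, 1)) +
    ggplot2::labs(title = paste0(attr(traj, "subfield"), " / ",
                                 attr(traj, "condition"),
                                 " representational trajectory"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hc_trajectory <- function(object, ...) plot_trajectory(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
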