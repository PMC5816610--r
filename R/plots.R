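#' Plot candidate binding sites along the scan window
#'
#' Sites are drawn at their TSS-relative centers against their PWM score;
#' when [rank_sites()] has added conservation, points are coloured by it
#' and the top-ranked site is labelled.
#'
#' @param object A `site_hits` tibble from [scan_pwm()] / [rank_sites()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_hits <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$center, y = .data$pwm_score))
  if ("conservation" %in% names(object)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$conservation, shape = .data$strand),
      size = 3
    ) +
      ggplot2::scale_colour_gradient(low = "grey70", high = "firebrick",
                                     limits = c(0, 1))
    top <- object[object$combined_rank == 1, , drop = FALSE]
    if (nrow(top) > 0) {
      p <- p + ggplot2::annotate("text", x = top$center[1],
                                 y = top$pwm_score[1],
                                 label = paste0("center ", top$center[1]),
                                 vjust = -1, size = 3)
    }
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$strand), size = 3)
  }
  p +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position relative to TSS (+1 = start)",
                  y = "PWM score (bits)",
                  title = attr(object, "motif") %||% "motif hits") +
    ggplot2::theme_minimal()
}

#' Plot a conservation profile
#'
#' @param object A `conservation_profile` from [conservation_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$identity)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "reference position", y = "column identity") +
    ggplot2::theme_minimal()
}

#' Plot fold changes with propagated standard deviations
#'
#' @param object A `fold_changes` tibble from [ddct_fold_changes()].
#' @param ... Unused.
#' @return A ggplot object (log2 fold-change scale).
#' @export
autoplot.fold_changes <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$condition, y = .data$fold_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$fold_change - .data$sd, 1e-3),
                   ymax = .data$fold_change + .data$sd),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(y = "fold change (2^-ddCt, log2 scale)") +
    ggplot2::theme_minimal()
}

#' Draw a cassette gene map
#'
#' Genes are drawn as arrows along the chromosome, coloured by their
#' first function label (white for unlabelled genes), one row per
#' cassette -- the usual way matched cassettes are displayed side by
#' side.
#'
#' @param cassettes Cassette tibble (rows from [assemble_cassettes()] or
#'   [cassette_fixtures()]).
#' @return A ggplot object.
#' @export
plot_cassette_map <- function(cassettes) {
  stopifnot(is.data.frame(cassettes), "genes" %in% names(cassettes))
  genes <- bind_rows(lapply(seq_len(nrow(cassettes)), function(i) {
    g <- cassettes$genes[[i]]
    g$cassette_id <- cassettes$cassette_id[i]
    g$label1 <- vapply(g$labels %||% rep(list(character(0)), nrow(g)),
                       function(l) if (length(l) > 0) l[1] else "none",
                       character(1))
    g
  }))
  ggplot2::ggplot(genes) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$cassette_id, yend = .data$cassette_id,
                   colour = .data$label1),
      linewidth = 6,
      arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt"))
    ) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "function label") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
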