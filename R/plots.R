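#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col facet_wrap
#'   scale_y_reverse scale_y_continuous scale_fill_manual labs theme_minimal
#'   theme element_text position_dodge2 ggsave expand_limits
NULL

band_legend <- function() {
  b <- risk_bands()
  paste(sprintf("SE %s = %s risk of random error",
                ifelse(is.infinite(b$upper),
                       sprintf("> %.2f", b$lower),
                       sprintf("%.2f to %.2f", b$lower, b$upper)),
                b$band),
        collapse = "; ")
}

default_outcome_colors <- function(outcomes) {
  base <- c("#d62728", "#1f77b4", "#e6c700", "#2ca02c",
            "#9467bd", "#8c564b", "#e377c2", "#7f7f7f")
  stats::setNames(rep_len(base, length(outcomes)), outcomes)
}

#' Plot matrix step I: evidence level against standard error
#'
#' Scatter of the studies for one outcome: random error (SE of the log
#' effect measure) on the horizontal axis, levels of evidence on the
#' vertical axis with the best evidence (level 1a) on top, so the most
#' reliable studies sit in the upper-left corner.
#'
#' @param object An `em_step1` tibble from [build_step1()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.em_step1 <- function(object, ...) {
  lv <- evidence_levels()
  dat <- as_tibble(object)
  ggplot(dat, aes(x = .data$se_ln, y = .data$level_rank)) +
    geom_point(size = 2.5, colour = "#1f77b4") +
    ggplot2::geom_text(aes(label = .data$study_id), hjust = -0.15, vjust = 0.5,
                       size = 3, check_overlap = TRUE) +
    scale_y_reverse(breaks = lv$rank, labels = lv$label,
                    limits = c(10.5, 0.5)) +
    expand_limits(x = 0) +
    labs(x = "Standard error (risk of random error)",
         y = "Level of evidence (risk of systematic error)",
         title = if (nrow(dat)) sprintf("Step I: %s", dat$outcome[1]) else "Step I") +
    theme_minimal()
}

#' Plot matrix step III: the benefit/harm Manhattan figure
#'
#' A two-panel bar landscape: bars are grouped by outcome (in importance
#' order), positioned within a group by evidence level, and their height
#' falls linearly with the standard error, so the tallest "skyscrapers" on
#' the left of the benefit panel — the upper west side — are the best
#' evidence. The caption states the five risk-of-random-error bands. Empty
#' panels are still drawn, making an empty benefit panel visible at a
#' glance.
#'
#' @param object An `em_step3` tibble from [build_step3()].
#' @param colors Optional named outcome-to-colour vector.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.em_step3 <- function(object, colors = NULL, ...) {
  dat <- as_tibble(object) |>
    mutate(panel = factor(.data$panel, levels = c("benefit", "harm"),
                          labels = c("a. Benefit", "b. Harm")),
           bar = interaction(.data$outcome, .data$level, .data$study_id,
                             drop = TRUE))
  outcomes <- levels(object$outcome) %||% unique(as.character(object$outcome))
  if (length(outcomes) == 0) outcomes <- "outcome"
  colors <- colors %||% default_outcome_colors(outcomes)
  has_bars <- nrow(dat) > 0
  if (!has_bars) {
    # empty panels are still drawn: an empty benefit side is a finding
    dat <- tibble(
      panel = factor(c("a. Benefit", "b. Harm")),
      outcome = factor(outcomes[1], levels = outcomes),
      height = 0, bar = c("x", "y"))
  }
  p <- ggplot(dat, aes(x = .data$outcome, y = .data$height,
                       group = .data$bar, fill = .data$outcome)) +
    (if (has_bars) {
      geom_col(position = position_dodge2(preserve = "single", padding = 0.05),
               colour = "grey30", linewidth = 0.2)
    } else {
      ggplot2::geom_blank()
    }) +
    facet_wrap(~panel, ncol = 2, drop = FALSE) +
    scale_fill_manual(values = colors, limits = outcomes, drop = FALSE,
                      name = "Outcome") +
    scale_y_continuous(limits = c(0, 1)) +
    ggplot2::scale_x_discrete(limits = outcomes, drop = FALSE) +
    labs(x = "Outcome (by importance)",
         y = sprintf("Bar height = (%.1f - SE) / %.1f",
                     attr(object, "se_cutoff") %||% 1,
                     attr(object, "se_cutoff") %||% 1),
         title = "Step III: Manhattan error matrix",
         caption = band_legend()) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1),
          plot.caption = element_text(size = 7))
  p
}

#' Render the Manhattan figure to a file
#'
#' @param bars An `em_step3` tibble from [build_step3()].
#' @param path Output path; the directory must exist and be writable.
#' @param format `"png"` or `"svg"`.
#' @param width,height,dpi Device size in inches and resolution.
#' @param colors Optional named outcome-to-colour vector.
#' @return `path`, invisibly.
#' @export
render_manhattan <- function(bars, path, format = c("png", "svg"),
                             width = 9, height = 5, dpi = 150, colors = NULL) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    stop_em("render", sprintf("Cannot write figure to '%s'.", path))
  }
  p <- autoplot(bars, colors = colors)
  dev <- if (format == "png") {
    if (requireNamespace("ragg", quietly = TRUE)) ragg::agg_png else grDevices::png
  } else {
    grDevices::svg
  }
  ggsave(path, plot = p, device = dev, width = width, height = height,
         dpi = dpi)
  invisible(path)
}
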