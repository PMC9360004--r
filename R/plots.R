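# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   geom_vline geom_abline labs theme_minimal scale_colour_manual
#'   facet_wrap
NULL

#' Quadrant plot of transcriptome vs translatome L2DE
#'
#' Scatter of `y` (footprint L2DE) against `x` (mRNA L2DE) for one or all
#' contrasts, coloured by regulation mode, with the mode band (`x - y =
#' +/- cutoff`) and axis cutoffs drawn.
#'
#' @param object A `translatome_classification` from [classify_dataset()].
#' @param contrast Contrast to show (`"acute"`, `"chronic"`, `"overall"`)
#'   or `NULL` for a facet per contrast.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot translatome_classification
#' @export
autoplot.translatome_classification <- function(object, contrast = NULL,
                                                ...) {
  dat <- object$modes
  if (!is.null(contrast)) dat <- dat[dat$contrast == contrast, ]
  c0 <- object$params$mode_cutoff
  cols <- c(up_both = "#d73027", up_occ_only = "#fc8d59",
            down_both = "#4575b4", down_occ_only = "#91bfdb",
            none = "grey70")
  ggplot(dat, aes(x = .data$x, y = .data$y, colour = .data$mode)) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_abline(intercept = c(-c0, c0), slope = 1, linetype = "dashed",
                colour = "grey40") +
    geom_hline(yintercept = c(-c0, c0), linetype = "dotted",
               colour = "grey60") +
    geom_vline(xintercept = c(-c0, c0), linetype = "dotted",
               colour = "grey60") +
    scale_colour_manual(values = cols) +
    (if (is.null(contrast)) facet_wrap(~contrast) else NULL) +
    labs(x = "mRNA abundance L2DE (x)",
         y = "ribosome footprint L2DE (y)",
         colour = "regulation mode") +
    theme_minimal()
}

#' Bar chart of per-group transcript counts
#'
#' Mirrors the marginal "n =" counts of a temporal-classification heatmap:
#' one bar per temporal group per channel.
#'
#' @param classification A `translatome_classification`.
#' @param drop_none Hide the unclassified bucket (default TRUE).
#' @return A ggplot object.
#' @export
plot_group_counts <- function(classification, drop_none = TRUE) {
  dat <- classification$summary |>
    filter(.data$channel %in% c("abundance", "occupancy"))
  if (drop_none) dat <- filter(dat, .data$group != "none")
  dat$group <- factor(dat$group,
                      levels = c(paste0("G", 1:12), "none"))
  ggplot(dat, aes(x = .data$group, y = .data$n, fill = .data$channel)) +
    geom_col() +
    facet_wrap(~channel, scales = "free_x") +
    labs(x = NULL, y = "transcripts") +
    theme_minimal()
}

#' Reading-frame distribution bar chart
#'
#' @param object A `frame_distribution` from [frame_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frame_distribution
#' @export
autoplot.frame_distribution <- function(object, ...) {
  dat <- tibble(frame = factor(0:2),
                fraction = c(object$f0, object$f1, object$f2))
  ggplot(dat, aes(x = .data$frame, y = .data$fraction)) +
    geom_col(fill = "#4575b4") +
    geom_hline(yintercept = 1 / 3, linetype = "dashed", colour = "grey50") +
    labs(x = "reading frame of P site", y = "fraction of footprints",
         subtitle = sprintf("n = %d reads in CDS", object$n_reads)) +
    theme_minimal()
}

#' Volcano plot of a cohort comparison
#'
#' @param object A `cohort_comparison` from [compare_geneset_expression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_comparison
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  lev <- attr(object, "groups")
  dat <- object |>
    filter(.data$tested) |>
    mutate(log2_fc = log2(.data$mean_alt / .data$mean_ref),
           neglog_fdr = -log10(pmax(.data$fdr, 1e-300)))
  ggplot(dat, aes(x = .data$log2_fc, y = .data$neglog_fdr,
                  colour = .data$significant)) +
    geom_point(alpha = 0.8) +
    geom_hline(yintercept = -log10(attr(object, "fdr_cutoff")),
               linetype = "dashed", colour = "grey50") +
    scale_colour_manual(values = c(`TRUE` = "#d73027", `FALSE` = "grey60")) +
    labs(x = sprintf("log2 fold change (%s / %s)", lev[2], lev[1]),
         y = "-log10 FDR", colour = sprintf("FDR <= %g",
                                            attr(object, "fdr_cutoff"))) +
    theme_minimal()
}
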