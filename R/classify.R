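# L2DE contrasts, temporal G1-G12 groups and the four regulation modes.
#
# All classification in this package is purely threshold-based on log2
# differential expression (L2DE) of replicate means; no test statistic
# enters group membership. Boundary conventions, fixed once:
#   * "up" / "down" are inclusive: L2DE >= cutoff / <= -cutoff;
#   * "no change" is strict: |L2DE| < cutoff;
#   * the regulation-mode band on x - y is half-open: -c <= (x - y) < c.

#' Log2 differential expression between two conditions
#'
#' `l2de(a, b)` is `log2(a / b)`: the log2 fold change of the numerator
#' condition over the denominator condition. At the default analysis cutoff
#' of 0.6, `2^0.6 = 1.52`, i.e. at least a 50% difference between the two
#' conditions.
#'
#' @param value_num,value_den Strictly positive expression values
#'   (typically replicate-mean RPKM); vectorized.
#' @return `log2(value_num / value_den)`.
#' @examples
#' l2de(4, 1)   # 2
#' l2de(3, 2)   # log2(1.5) = 0.585
#' @export
l2de <- function(value_num, value_den) {
  if (any(!is.finite(value_num)) || any(!is.finite(value_den)) ||
      any(value_num <= 0) || any(value_den <= 0)) {
    stop_tl("l2de requires strictly positive finite inputs")
  }
  log2(value_num / value_den)
}

# Shared temporal rule geometry. Returns one of the six pattern labels or
# "none". acute/chronic/overall are the L2DEs of the acute (stress/control),
# chronic (late/early stress) and overall (late stress/control) contrasts.
temporal_pattern <- function(acute, chronic, overall, cutoff) {
  assert_finite(acute, "acute L2DE")
  assert_finite(chronic, "chronic L2DE")
  assert_finite(overall, "overall L2DE")
  if (cutoff <= 0) stop_tl("cutoff must be positive")
  up_a <- acute >= cutoff
  dn_a <- acute <= -cutoff
  nc_a <- abs(acute) < cutoff
  up_c <- chronic >= cutoff
  dn_c <- chronic <= -cutoff
  dplyr::case_when(
    up_a & up_c ~ "up_up",
    up_a & dn_c ~ "up_down",
    nc_a & up_c & overall >= cutoff ~ "none_up",
    dn_a & dn_c ~ "down_down",
    dn_a & up_c ~ "down_up",
    nc_a & dn_c & overall <= -cutoff ~ "none_down",
    .default = "none"
  )
}

#' Temporal classification of mRNA abundance changes (G1-G6)
#'
#' Assigns each transcript a temporal group from the signs of its acute,
#' chronic and overall abundance L2DEs against a symmetric cutoff
#' (default 0.32, i.e. a 25% change):
#' G1 up/up, G2 up/down, G3 no-change/up with overall up, G4 down/down,
#' G5 down/up, G6 no-change/down with overall down; `"none"` otherwise.
#' G2 and G5 place no condition on the overall contrast.
#'
#' @param acute,chronic,overall L2DE vectors for the acute
#'   (stress vs control), chronic (late vs early stress) and overall
#'   (late stress vs control) contrasts.
#' @param cutoff Positive threshold; up/down are inclusive, no-change strict.
#' @return Character vector in `c("G1", ..., "G6", "none")`.
#' @examples
#' classify_temporal_abundance(0.5, 0.5, 1.0)   # "G1"
#' classify_temporal_abundance(0.0, 0.7, 0.7)   # "G3"
#' classify_temporal_abundance(-0.5, 0.8, 0.3)  # "G5"
#' @export
classify_temporal_abundance <- function(acute, chronic, overall,
                                        cutoff = 0.32) {
  map <- c(up_up = "G1", up_down = "G2", none_up = "G3",
           down_down = "G4", down_up = "G5", none_down = "G6",
           none = "none")
  unname(map[temporal_pattern(acute, chronic, overall, cutoff)])
}

#' Temporal classification of ribosome-occupancy changes (G7-G12)
#'
#' Same rule geometry as [classify_temporal_abundance()] applied to
#' occupancy L2DEs, with the group codes in their conventional order:
#' G7 up/up, G8 up/down, G9 no-change/up with overall up, G10
#' no-change/down with overall down, G11 down/up, G12 down/down. Note the
#' ordering differs from the abundance codes (G10 is the no-change/down
#' class, G12 the down/down class).
#'
#' @inheritParams classify_temporal_abundance
#' @return Character vector in `c("G7", ..., "G12", "none")`.
#' @examples
#' classify_temporal_occupancy(0.4, 0.4, 0.8)    # "G7"
#' classify_temporal_occupancy(0.0, -0.4, -0.4)  # "G10"
#' @export
classify_temporal_occupancy <- function(acute, chronic, overall,
                                        cutoff = 0.32) {
  map <- c(up_up = "G7", up_down = "G8", none_up = "G9",
           none_down = "G10", down_up = "G11", down_down = "G12",
           none = "none")
  unname(map[temporal_pattern(acute, chronic, overall, cutoff)])
}

#' Joint transcriptional/translational regulation mode
#'
#' Classifies a transcript from its transcriptome L2DE `x` and ribosome
#' footprint L2DE `y` for one contrast, using a band of half-width `cutoff`
#' (default 0.6, at least a 50% change) around the diagonal:
#' \describe{
#'   \item{`up_both`}{`-c <= (x - y) < c`, `x >= c`, `y >= c` — coordinate
#'     up-regulation of abundance and occupancy.}
#'   \item{`up_occ_only`}{`(x - y) < -c`, `y > c` — translational
#'     up-regulation without a matching abundance change.}
#'   \item{`down_both`}{`-c <= (x - y) < c`, `x <= -c`, `y <= -c`.}
#'   \item{`down_occ_only`}{`(x - y) > c`, `y < -c`.}
#' }
#' Rules are applied in this order; anything else is `"none"`. The band on
#' `x - y` is half-open, so `x - y = -c` is inside it and `x - y = c`
#' outside.
#'
#' @param x Transcriptome (mRNA abundance) L2DE; vectorized.
#' @param y Translatome (ribosome footprint) L2DE; vectorized.
#' @param cutoff Positive threshold (default 0.6).
#' @return Character vector in
#'   `c("up_both", "up_occ_only", "down_both", "down_occ_only", "none")`.
#' @examples
#' classify_regulation_mode(1.0, 0.8)   # "up_both"
#' classify_regulation_mode(0.0, 1.0)   # "up_occ_only"
#' classify_regulation_mode(0.0, -1.0)  # "down_occ_only"
#' @export
classify_regulation_mode <- function(x, y, cutoff = 0.6) {
  assert_finite(x, "x"); assert_finite(y, "y")
  if (cutoff <= 0) stop_tl("cutoff must be positive")
  d <- x - y
  in_band <- d >= -cutoff & d < cutoff
  dplyr::case_when(
    in_band & x >= cutoff & y >= cutoff ~ "up_both",
    d < -cutoff & y > cutoff ~ "up_occ_only",
    in_band & x <= -cutoff & y <= -cutoff ~ "down_both",
    d > cutoff & y < -cutoff ~ "down_occ_only",
    .default = "none"
  )
}

#' Classify every detected transcript across a stress time course
#'
#' Runs the whole classification stage: computes replicate-mean RPKM per
#' condition and assay, forms the three L2DE contrasts (acute = stress vs
#' control, chronic = late vs early stress, overall = late stress vs
#' control) for the transcriptome (`x`), the translatome (`y`) and the
#' occupancy ratio (`occ_l2de = log2` of the occupancy ratio, which equals
#' `y - x` when occupancy is RPKM-based), then assigns temporal groups
#' G1-G6 (abundance) and G7-G12 (occupancy) and a regulation mode per
#' contrast.
#'
#' @param rpkm Long expression tibble from [compute_rpkm()], both assays.
#' @param occupancy Occupancy tibble from [compute_occupancy()]; its
#'   transcripts define the detected universe.
#' @param conditions Named character vector with entries `control`, `acute`
#'   and `chronic` naming the three conditions in the metadata.
#' @param group_cutoff L2DE cutoff for the temporal groups (default 0.32).
#' @param mode_cutoff L2DE cutoff for the regulation modes (default 0.6).
#' @param mode_y Which signal plays `y` in the regulation-mode rules:
#'   `"ribo"` (default; footprint L2DE, matching the symbol definitions of
#'   the rules) or `"occupancy"` (occupancy L2DE, for sensitivity analysis).
#' @return An object of class `translatome_classification`: a list with
#'   tibbles `l2de` (one row per transcript x contrast), `groups` (temporal
#'   assignments), `modes` (regulation mode per transcript x contrast) and
#'   `summary` (per-group and per-mode counts), plus the parameters used.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
classify_dataset <- function(rpkm, occupancy,
                             conditions = c(control = "CON",
                                            acute = "CPA1",
                                            chronic = "CPA18"),
                             group_cutoff = 0.32, mode_cutoff = 0.6,
                             mode_y = c("ribo", "occupancy")) {
  mode_y <- match.arg(mode_y)
  if (!all(c("control", "acute", "chronic") %in% names(conditions))) {
    stop_tl("conditions must name control, acute and chronic")
  }
  missing_cond <- setdiff(conditions, unique(rpkm$condition))
  if (length(missing_cond) > 0) {
    stop_tl("condition(s) absent from expression data: %s",
            paste(missing_cond, collapse = ", "))
  }
  detected <- unique(occupancy$transcript_id)

  means <- rpkm |>
    filter(.data$transcript_id %in% detected,
           .data$condition %in% conditions) |>
    group_by(.data$transcript_id, .data$condition, .data$assay) |>
    summarise(mean_rpkm = mean(.data$rpkm), .groups = "drop")

  wide <- means |>
    tidyr::pivot_wider(names_from = c("assay", "condition"),
                       values_from = "mean_rpkm", names_sep = ".")
  occ_wide <- occupancy |>
    filter(.data$condition %in% conditions) |>
    select("transcript_id", "condition", "occupancy") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "occupancy",
                       names_prefix = "occ.")

  col <- function(assay, cond) wide[[paste(assay, conditions[[cond]],
                                           sep = ".")]]
  occ_col <- function(cond) occ_wide[[paste0("occ.", conditions[[cond]])]]
  occ_wide <- occ_wide[match(wide$transcript_id, occ_wide$transcript_id), ]

  contrast_def <- list(acute = c("acute", "control"),
                       chronic = c("chronic", "acute"),
                       overall = c("chronic", "control"))
  l2de_tbl <- purrr::imap_dfr(contrast_def, function(pair, label) {
    tibble(
      transcript_id = wide$transcript_id,
      contrast = label,
      numerator = unname(conditions[[pair[1]]]),
      denominator = unname(conditions[[pair[2]]]),
      x = l2de(col("mrna", pair[1]), col("mrna", pair[2])),
      y = l2de(col("ribo", pair[1]), col("ribo", pair[2])),
      occ_l2de = l2de(occ_col(pair[1]), occ_col(pair[2]))
    )
  })

  by_contrast <- split(l2de_tbl, l2de_tbl$contrast)
  groups <- tibble(
    transcript_id = wide$transcript_id,
    abundance_group = classify_temporal_abundance(
      by_contrast$acute$x, by_contrast$chronic$x, by_contrast$overall$x,
      cutoff = group_cutoff),
    occupancy_group = classify_temporal_occupancy(
      by_contrast$acute$occ_l2de, by_contrast$chronic$occ_l2de,
      by_contrast$overall$occ_l2de, cutoff = group_cutoff)
  )

  modes <- l2de_tbl |>
    mutate(y_used = if (mode_y == "ribo") .data$y else .data$occ_l2de,
           mode = classify_regulation_mode(.data$x, .data$y_used,
                                           cutoff = mode_cutoff)) |>
    select("transcript_id", "contrast", "x", y = "y_used", "mode")

  summary_tbl <- bind_rows(
    groups |> count(group = .data$abundance_group) |>
      mutate(channel = "abundance", contrast = NA_character_),
    groups |> count(group = .data$occupancy_group) |>
      mutate(channel = "occupancy", contrast = NA_character_),
    modes |> count(.data$contrast, group = .data$mode) |>
      mutate(channel = "mode")
  ) |>
    select("channel", "contrast", "group", "n")

  structure(
    list(l2de = l2de_tbl, groups = groups, modes = modes,
         summary = summary_tbl,
         params = list(conditions = conditions, group_cutoff = group_cutoff,
                       mode_cutoff = mode_cutoff, mode_y = mode_y,
                       n_transcripts = length(detected))),
    class = "translatome_classification"
  )
}

#' @export
print.translatome_classification <- function(x, ...) {
  cat("Translatome classification of", x$params$n_transcripts,
      "detected transcripts\n")
  cat("  conditions:", paste(names(x$params$conditions),
                             x$params$conditions, sep = "=",
                             collapse = " "), "\n")
  cat("  cutoffs: group", x$params$group_cutoff,
      "| mode", x$params$mode_cutoff, "(y =", x$params$mode_y, ")\n")
  grp <- x$summary |> filter(.data$channel != "mode", .data$group != "none")
  cat("  classified:", sum(grp$n), "group assignments across",
      nrow(grp), "groups\n")
  invisible(x)
}

#' @rdname classify_dataset
#' @param x A `translatome_classification` object.
#' @param ... Unused.
#' @method tidy translatome_classification
#' @export
tidy.translatome_classification <- function(x, ...) {
  x$l2de |>
    left_join(x$groups, by = "transcript_id") |>
    left_join(x$modes |> select("transcript_id", "contrast", "mode"),
              by = c("transcript_id", "contrast"))
}

#' @rdname classify_dataset
#' @method glance translatome_classification
#' @export
glance.translatome_classification <- function(x, ...) {
  grp <- function(ch) {
    s <- x$summary |> filter(.data$channel == ch, .data$group != "none")
    sum(s$n)
  }
  tibble(
    n_transcripts = x$params$n_transcripts,
    n_abundance_grouped = grp("abundance"),
    n_occupancy_grouped = grp("occupancy"),
    group_cutoff = x$params$group_cutoff,
    mode_cutoff = x$params$mode_cutoff
  )
}
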