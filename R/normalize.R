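# RPKM, detection filtering and ribosome occupancy.

#' Compute RPKM from a long count table
#'
#' RPKM = reads per kilobase of transcript per million total aligned reads:
#' `count / (length/1000) / (total/1e6)` where `total` is the column sum of
#' the input table for that sample. Totals are taken on the table as given,
#' before any detection filtering, so RPKM is exactly linear in the counts
#' of a sample.
#'
#' @param counts Long count tibble (see [read_count_table()]).
#' @param model Gene model covering every transcript in `counts`.
#' @return The input tibble with an added `length` and `rpkm` column.
#' @examples
#' model <- tibble::tibble(transcript_id = "tx1", gene_id = "g1",
#'   length = 2000L, cds_start = 0L, cds_end = 300L)
#' counts <- tibble::tibble(transcript_id = "tx1", sample_id = "s1",
#'   assay = "mrna", condition = "CON", replicate = 1L, count = 100)
#' # single-transcript library: total = 100 reads
#' compute_rpkm(counts, model)$rpkm  # 100 / 2 / 1e-4 = 500000
#' @export
compute_rpkm <- function(counts, model) {
  counts <- validate_counts(counts, model = validate_gene_model(model))
  totals <- counts |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$count), .groups = "drop")
  if (any(totals$total == 0)) {
    stop_tl("sample(s) with zero total reads: %s",
            paste(totals$sample_id[totals$total == 0], collapse = ", "))
  }
  counts |>
    inner_join(model[, c("transcript_id", "gene_id", "length")],
               by = "transcript_id") |>
    inner_join(totals, by = "sample_id") |>
    mutate(rpkm = .data$count / (.data$length / 1000) /
             (.data$total / 1e6)) |>
    select(-"total")
}

#' Strict all-replicates detection filter
#'
#' A transcript is "detected" when it has signal (RPKM > 0, i.e. at least
#' one aligned read) in every replicate of every condition in *both* assays.
#' A transcript nonzero in 17 of 18 samples is excluded. This mirrors the
#' practice of keeping only genes identified in all independent experiments
#' before downstream contrasts, so that all log-ratios are finite.
#'
#' @param rpkm Long expression tibble from [compute_rpkm()] containing both
#'   `mrna` and `ribo` assays.
#' @return A tibble with the single column `transcript_id`.
#' @export
detected_transcripts <- function(rpkm) {
  assert_cols(rpkm, c("transcript_id", "assay", "rpkm"), "expression table")
  assays <- unique(rpkm$assay)
  if (!all(c("mrna", "ribo") %in% assays)) {
    stop_tl("detection filter needs both assays; found: %s",
            paste(assays, collapse = ", "))
  }
  n_samples <- n_distinct(rpkm$sample_id)
  rpkm |>
    group_by(.data$transcript_id) |>
    summarise(ok = n() == n_samples && all(.data$rpkm > 0),
              .groups = "drop") |>
    filter(.data$ok) |>
    select("transcript_id")
}

#' Per-condition ribosome occupancy
#'
#' Ribosome occupancy of a transcript in a condition is the mean Ribo-seq
#' signal across replicates divided by the mean mRNA-seq signal across
#' replicates; it is the package's proxy for translation efficiency. The
#' default basis is RPKM (occupancy is a normalized quantity); `basis =
#' "raw"` takes the ratio of mean raw counts instead, preserving the literal
#' count-based reading of the definition.
#'
#' @param rpkm Long expression tibble from [compute_rpkm()], both assays.
#' @param detected Tibble or character vector of detected transcript ids
#'   (see [detected_transcripts()]); occupancy is computed only for these,
#'   which guarantees strictly positive mRNA means.
#' @param basis `"rpkm"` (default) or `"raw"`.
#' @return A tibble with `transcript_id`, `condition`, `mrna_mean`,
#'   `ribo_mean`, `occupancy`.
#' @export
compute_occupancy <- function(rpkm, detected, basis = c("rpkm", "raw")) {
  basis <- match.arg(basis)
  assert_cols(rpkm, c("transcript_id", "assay", "condition", "rpkm",
                      "count"), "expression table")
  ids <- if (is.data.frame(detected)) detected$transcript_id else detected
  value_col <- if (basis == "rpkm") "rpkm" else "count"
  occ <- rpkm |>
    filter(.data$transcript_id %in% ids) |>
    group_by(.data$transcript_id, .data$condition, .data$assay) |>
    summarise(mean_value = mean(.data[[value_col]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "mean_value")
  assert_cols(occ, c("mrna", "ribo"), "occupancy input")
  if (any(occ$mrna == 0)) {
    stop_tl("zero mRNA mean for requested transcript(s): %s (not detected?)",
            paste(head(unique(occ$transcript_id[occ$mrna == 0]), 5),
                  collapse = ", "))
  }
  occ |>
    transmute(.data$transcript_id, .data$condition,
              mrna_mean = .data$mrna, ribo_mean = .data$ribo,
              occupancy = .data$ribo / .data$mrna)
}
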