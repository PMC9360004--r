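# Tabular input readers and validators.
#
# On-disk dialects: UTF-8 TSV with a header for the gene model, counts and
# sample metadata; standard GMT for gene sets. Transcript coordinates are
# transcript-local, 0-based, half-open [cds_start, cds_end). Identifiers are
# case-sensitive. Counts are integers: fractional multi-mapped weighting is
# an upstream concern and is rejected here.

#' Validate a gene-model table
#'
#' Checks the structural invariants of a gene model: unique transcript ids,
#' `0 <= cds_start < cds_end <= length`, and a CDS length divisible by 3
#' (violations of the last are reported as a warning and kept, since
#' annotation references do contain such transcripts).
#'
#' @param model A data frame with columns `transcript_id`, `gene_id`,
#'   `length`, `cds_start`, `cds_end`.
#' @return The validated model as a tibble, invisibly usable in pipes.
#' @export
validate_gene_model <- function(model) {
  assert_cols(model, c("transcript_id", "gene_id", "length",
                       "cds_start", "cds_end"), "gene model")
  model <- as_tibble(model)
  dup <- model$transcript_id[duplicated(model$transcript_id)]
  if (length(dup) > 0) {
    stop_tl("duplicate transcript_id in gene model: %s",
            paste(unique(dup), collapse = ", "))
  }
  if (any(model$length <= 0)) stop_tl("non-positive transcript length")
  bad <- which(!(model$cds_start >= 0 &
                 model$cds_start < model$cds_end &
                 model$cds_end <= model$length))
  if (length(bad) > 0) {
    stop_tl("CDS outside transcript bounds for %s",
            paste(model$transcript_id[bad], collapse = ", "))
  }
  off_frame <- which((model$cds_end - model$cds_start) %% 3 != 0)
  if (length(off_frame) > 0) {
    warn_tl("CDS length not divisible by 3 for %s (rows retained)",
            paste(model$transcript_id[off_frame], collapse = ", "))
  }
  model
}

#' Read a gene-model TSV
#'
#' The gene model is the coordinate authority for normalization and QC: it
#' maps each transcript to its gene, its length in nucleotides and its CDS
#' interval in 0-based half-open transcript coordinates.
#'
#' @param path Path to a TSV with header `transcript_id`, `gene_id`,
#'   `length`, `cds_start`, `cds_end`.
#' @return A validated tibble; row order of the file is preserved.
#' @export
read_gene_model <- function(path) {
  model <- readr::read_tsv(
    path, comment = "#", progress = FALSE,
    col_types = readr::cols(
      transcript_id = readr::col_character(),
      gene_id = readr::col_character(),
      length = readr::col_integer(),
      cds_start = readr::col_integer(),
      cds_end = readr::col_integer()
    )
  )
  validate_gene_model(model)
}

#' Validate a sample-metadata table
#'
#' @param samples Data frame with `sample_id`, `assay` (one of `"mrna"`,
#'   `"ribo"`), `condition`, `replicate`.
#' @return The validated tibble.
#' @export
validate_samples <- function(samples) {
  assert_cols(samples, c("sample_id", "assay", "condition", "replicate"),
              "sample metadata")
  samples <- as_tibble(samples)
  if (anyDuplicated(samples$sample_id)) {
    stop_tl("duplicate sample_id in metadata")
  }
  bad_assay <- setdiff(unique(samples$assay), c("mrna", "ribo"))
  if (length(bad_assay) > 0) {
    stop_tl("unknown assay value(s): %s", paste(bad_assay, collapse = ", "))
  }
  if (any(samples$replicate < 1)) stop_tl("replicate must be >= 1")
  samples
}

#' Validate a long-format count table
#'
#' @param counts Data frame with `transcript_id`, `sample_id`, `assay`,
#'   `condition`, `replicate`, `count`.
#' @param model Optional gene model; when given, transcript ids must be a
#'   subset of the model's.
#' @return The validated tibble.
#' @export
validate_counts <- function(counts, model = NULL) {
  assert_cols(counts, c("transcript_id", "sample_id", "assay", "condition",
                        "replicate", "count"), "count table")
  counts <- as_tibble(counts)
  if (any(counts$count < 0)) stop_tl("negative count")
  if (any(counts$count != trunc(counts$count))) {
    stop_tl("non-integer count (fractional read weighting is not supported)")
  }
  if (anyDuplicated(counts[, c("transcript_id", "sample_id")])) {
    stop_tl("duplicate (transcript_id, sample_id) rows in count table")
  }
  if (!is.null(model)) {
    unknown <- setdiff(unique(counts$transcript_id), model$transcript_id)
    if (length(unknown) > 0) {
      stop_tl("transcripts absent from gene model: %s",
              paste(head(unknown, 5), collapse = ", "))
    }
  }
  counts
}

#' Read a count matrix and its sample metadata into a long tibble
#'
#' The counts file is a TSV whose first column is `transcript_id` and whose
#' remaining columns are sample ids; the metadata file is a TSV keyed by
#' `sample_id` with `assay`, `condition` and `replicate` columns. Every
#' sample column must be described in the metadata; metadata rows for
#' samples not present in the counts are ignored with a warning.
#'
#' @param path Path to the counts TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @return A long tibble with columns `transcript_id`, `sample_id`, `assay`,
#'   `condition`, `replicate`, `count`.
#' @export
read_count_table <- function(path, meta_path) {
  wide <- readr::read_tsv(path, comment = "#", progress = FALSE,
                          col_types = readr::cols(
                            transcript_id = readr::col_character(),
                            .default = readr::col_double()
                          ))
  assert_cols(wide, "transcript_id", "count table")
  meta <- readr::read_tsv(meta_path, comment = "#", progress = FALSE,
                          col_types = readr::cols(
                            sample_id = readr::col_character(),
                            assay = readr::col_character(),
                            condition = readr::col_character(),
                            replicate = readr::col_integer()
                          ))
  meta <- validate_samples(meta)
  sample_ids <- setdiff(names(wide), "transcript_id")
  missing_meta <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_meta) > 0) {
    stop_tl("sample(s) in counts without metadata: %s",
            paste(missing_meta, collapse = ", "))
  }
  extra <- setdiff(meta$sample_id, sample_ids)
  if (length(extra) > 0) {
    warn_tl("metadata rows for sample(s) absent from counts ignored: %s",
            paste(extra, collapse = ", "))
  }
  long <- tidyr::pivot_longer(wide, -"transcript_id",
                              names_to = "sample_id", values_to = "count")
  long <- inner_join(long, meta, by = "sample_id")
  long <- select(long, "transcript_id", "sample_id", "assay", "condition",
                 "replicate", "count")
  validate_counts(long)
}

#' Write a long count tibble back to the wide counts + metadata dialect
#'
#' @param counts Long count tibble as returned by [read_count_table()].
#' @param path,meta_path Output paths for counts and metadata TSVs.
#' @param provenance Optional `# key=value` header entries.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, meta_path,
                              provenance = character()) {
  counts <- validate_counts(counts)
  wide <- tidyr::pivot_wider(
    counts[, c("transcript_id", "sample_id", "count")],
    names_from = "sample_id", values_from = "count"
  )
  write_tsv_prov(wide, path, provenance)
  meta <- distinct(counts, .data$sample_id, .data$assay, .data$condition,
                   .data$replicate)
  write_tsv_prov(meta, meta_path, provenance)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member gene ids. Duplicate members within a
#' line are deduplicated; duplicate set names or lines with fewer than three
#' fields are errors.
#'
#' @param path Path to a GMT file.
#' @return A long tibble with columns `set_name`, `description`, `gene_id`;
#'   zero rows for an empty file.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(set_name = character(), description = character(),
                  gene_id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    stop_tl("GMT line %d has fewer than 3 fields",
            which(n_fields < 3)[1])
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop_tl("duplicate gene-set name in GMT: %s",
            names_[duplicated(names_)][1])
  }
  purrr::map_dfr(fields, function(f) {
    tibble(set_name = f[[1]], description = f[[2]],
           gene_id = unique(f[-(1:2)]))
  })
}

#' Write a gene-set collection as GMT
#'
#' @param sets Long tibble with `set_name`, `description`, `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  assert_cols(sets, c("set_name", "description", "gene_id"), "gene sets")
  lines <- sets |>
    group_by(.data$set_name) |>
    summarise(line = paste(c(.data$set_name[1], .data$description[1],
                             unique(.data$gene_id)), collapse = "\t"),
              .groups = "drop")
  writeLines(lines$line, path, useBytes = FALSE)
  invisible(path)
}

#' Read footprint records from a 3-column TSV
#'
#' Footprints are transcriptome-aligned ribosome-protected fragments,
#' reduced to `(transcript_id, five_prime_pos, length)` where
#' `five_prime_pos` is the 0-based transcript coordinate of the read 5' end.
#' Producing this table from an aligner's transcript-space output is a
#' one-line awk/bioframe exercise and is out of scope here.
#'
#' @param path Path to the TSV.
#' @param model Optional gene model used to check that reads fall inside
#'   their transcript.
#' @return A tibble with columns `transcript_id`, `five_prime_pos`, `length`.
#' @export
read_footprints <- function(path, model = NULL) {
  fp <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        col_types = readr::cols(
                          transcript_id = readr::col_character(),
                          five_prime_pos = readr::col_integer(),
                          length = readr::col_integer()
                        ))
  if (any(fp$five_prime_pos < 0)) stop_tl("negative footprint position")
  if (!is.null(model)) {
    fp2 <- inner_join(fp, model[, c("transcript_id", "length")],
                      by = "transcript_id", suffix = c("", "_tx"))
    if (any(fp2$five_prime_pos + fp2$length > fp2$length_tx)) {
      stop_tl("footprint extends past transcript end")
    }
  }
  fp
}
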