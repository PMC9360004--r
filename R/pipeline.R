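# Stage orchestration behind a declarative config.

default_config <- function() {
  list(
    conditions = list(control = "CON", acute = "CPA1", chronic = "CPA18"),
    group_cutoff = 0.32,
    mode_cutoff = 0.6,
    mode_y = "ribo",
    occupancy_basis = "rpkm",
    fdr_cutoff = 1e-3,
    p_site_offset = 12,
    footprint_length = c(20, 40),
    seed = 1
  )
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a single declarative YAML file (or an equivalent
#' named list). Every analysis threshold surfaces as a named key with its
#' standard value as default: `group_cutoff` 0.32, `mode_cutoff` 0.6,
#' `fdr_cutoff` 1e-3, `footprint_length` 20-40, `p_site_offset` 12,
#' `occupancy_basis` "rpkm". Input paths: `counts`, `metadata`,
#' `gene_model`, optionally `gmt` and `footprints`; `outdir` names the
#' report directory.
#'
#' @param config Path to a YAML file or a named list.
#' @return The validated configuration list with defaults filled in.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  needed <- c("counts", "metadata", "gene_model", "outdir")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    stop_tl("config is missing key(s): %s", paste(missing, collapse = ", "))
  }
  if (!all(c("control", "acute", "chronic") %in% names(cfg$conditions))) {
    stop_tl("config conditions must name control, acute and chronic")
  }
  for (key in c("group_cutoff", "mode_cutoff", "fdr_cutoff")) {
    if (cfg[[key]] <= 0) stop_tl("config %s must be positive", key)
  }
  cfg
}

#' Pick a representative transcript per gene
#'
#' Gene-level summaries of a transcript-level classification need one
#' transcript per gene; the representative is the transcript with the
#' highest mean control mRNA RPKM (ties broken by transcript order).
#'
#' @param rpkm Long expression tibble from [compute_rpkm()].
#' @param control Name of the control condition.
#' @return A tibble `gene_id`, `transcript_id` with one row per gene.
#' @export
gene_representatives <- function(rpkm, control = "CON") {
  assert_cols(rpkm, c("transcript_id", "gene_id", "assay", "condition",
                      "rpkm"), "expression table")
  rpkm |>
    filter(.data$assay == "mrna", .data$condition == control) |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(mean_rpkm = mean(.data$rpkm), .groups = "drop") |>
    group_by(.data$gene_id) |>
    slice_max(.data$mean_rpkm, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("gene_id", "transcript_id")
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes every stage in order — read and validate inputs, RPKM,
#' detection filter, occupancy, L2DE classification, optional gene-set
#' enrichment of each temporal group, optional footprint QC — and writes
#' audited TSV report tables plus a provenance log (config hash, package
#' version, seed, record counts in and out of every filter) to the output
#' directory. Re-running with the same config reproduces identical tables.
#'
#' @param config Path to a YAML config or a named list (see
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with the classification object, the occupancy
#'   table and the paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("translatome pipeline v%s",
                         as.character(utils::packageVersion("translatome"))),
                 sprintf("config_hash=%s", rlang::hash(cfg)),
                 sprintf("seed=%s", cfg$seed))
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  prov <- c(config_hash = rlang::hash(cfg))
  out_path <- function(name) file.path(cfg$outdir, name)
  paths <- character()
  emit <- function(tbl, name) {
    p <- out_path(name)
    write_tsv_prov(tbl, p, prov)
    paths <<- c(paths, p)
  }

  model <- read_gene_model(cfg$gene_model)
  counts <- read_count_table(cfg$counts, cfg$metadata)
  note("input: %d transcripts x %d samples", n_distinct(counts$transcript_id),
       n_distinct(counts$sample_id))

  conds <- unlist(cfg$conditions)
  missing_cond <- setdiff(conds, unique(counts$condition))
  if (length(missing_cond) > 0) {
    stop_tl("stage config: condition(s) not in metadata: %s",
            paste(missing_cond, collapse = ", "))
  }

  rpkm <- compute_rpkm(counts, model)
  emit(rpkm, "expression.tsv")

  detected <- detected_transcripts(rpkm)
  note("detection filter: %d of %d transcripts retained", nrow(detected),
       n_distinct(rpkm$transcript_id))

  occ <- compute_occupancy(rpkm, detected, basis = cfg$occupancy_basis)
  emit(occ, "occupancy.tsv")

  cls <- classify_dataset(rpkm, occ, conditions = conds,
                          group_cutoff = cfg$group_cutoff,
                          mode_cutoff = cfg$mode_cutoff,
                          mode_y = cfg$mode_y)
  emit(cls$l2de, "l2de.tsv")
  emit(cls$groups, "groups.tsv")
  emit(cls$modes, "modes.tsv")
  emit(cls$summary, "summary.tsv")
  grouped <- sum(cls$summary$n[cls$summary$channel != "mode" &
                                 cls$summary$group != "none"])
  note("classification: %d group assignments", grouped)

  if (!is.null(cfg$gmt)) {
    sets <- read_gmt(cfg$gmt)
    reps <- gene_representatives(rpkm, control = cfg$conditions$control)
    gene_groups <- cls$groups |>
      inner_join(reps, by = "transcript_id")
    universe <- unique(gene_groups$gene_id)
    enr <- bind_rows(
      gene_groups |>
        filter(.data$abundance_group != "none") |>
        group_by(group = .data$abundance_group) |>
        group_modify(~ enrich_genesets(.x$gene_id, universe, sets)) |>
        ungroup(),
      gene_groups |>
        filter(.data$occupancy_group != "none") |>
        group_by(group = .data$occupancy_group) |>
        group_modify(~ enrich_genesets(.x$gene_id, universe, sets)) |>
        ungroup()
    )
    emit(enr, "enrichment.tsv")
    note("enrichment: %d group x set tests", nrow(enr))
  }

  if (!is.null(cfg$footprints)) {
    fp <- read_footprints(cfg$footprints, model)
    n0 <- nrow(fp)
    fp <- fp[fp$length >= cfg$footprint_length[1] &
               fp$length <= cfg$footprint_length[2], ]
    note("footprint length filter [%d, %d]: %d of %d reads retained",
         cfg$footprint_length[1], cfg$footprint_length[2], nrow(fp), n0)
    fd <- frame_distribution(fp, model,
                             p_site_offset = cfg$p_site_offset)
    emit(as_tibble(fd), "qc_frame.tsv")
    note("frame QC: f0=%.4f on %d reads", fd$f0, fd$n_reads)
  }

  writeLines(log_lines, out_path("log.txt"))
  invisible(list(classification = cls, occupancy = occ, rpkm = rpkm,
                 paths = paths, log = log_lines))
}

#' Write a complete synthetic fixture directory
#'
#' Materializes a [simulate_experiment()] result (plus synthetic footprints
#' and a small synthetic gene-set collection) as the on-disk inputs the
#' pipeline consumes: `counts.tsv`, `metadata.tsv`, `gene_model.tsv`,
#' `truth.tsv`, `footprints.tsv`, `sets.gmt` and a ready-to-run
#' `config.yaml`.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @param n_footprints Number of synthetic Ribo-seq footprints.
#' @param frame0_fraction Planted frame-0 fraction of the footprints.
#' @param seed Integer seed for the footprints and gene-set draw.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(sim, dir, n_footprints = 20000,
                              frame0_fraction = 0.9, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(dir, name)
  prov <- c(generator = "translatome::write_fixture_dir",
            seed = as.character(seed))
  write_tsv_prov(sim$model, p("gene_model.tsv"), prov)
  write_count_table(sim$counts, p("counts.tsv"), p("metadata.tsv"), prov)
  write_tsv_prov(sim$truth, p("truth.tsv"), prov)
  fp <- generate_footprints(sim$model, n_footprints,
                            frame0_fraction = frame0_fraction, seed = seed)
  write_tsv_prov(fp, p("footprints.tsv"), prov)
  # synthetic stand-in pathway collection: one set enriched in planted
  # chronic-up genes, one in planted down genes, one background draw
  set.seed(split_seed(seed, "fixture_gmt"))
  up_genes <- sim$truth$gene_id[sim$truth$abundance_group %in%
                                  c("G1", "G3")]
  down_genes <- sim$truth$gene_id[sim$truth$abundance_group %in%
                                    c("G4", "G6")]
  all_genes <- sim$truth$gene_id
  pick <- function(pool, n) sample(pool, min(n, length(pool)))
  sets <- bind_rows(
    tibble(set_name = "synthetic_ER_protein_processing",
           description = "synthetic pathway enriched in planted chronic-up genes",
           gene_id = unique(c(pick(up_genes, 80), pick(all_genes, 40)))),
    tibble(set_name = "synthetic_beta_cell_identity",
           description = "synthetic pathway enriched in planted down genes",
           gene_id = unique(c(pick(down_genes, 60), pick(all_genes, 30)))),
    tibble(set_name = "synthetic_background",
           description = "random background set",
           gene_id = pick(all_genes, 100))
  )
  write_gmt(sets, p("sets.gmt"))
  cfg <- list(counts = p("counts.tsv"), metadata = p("metadata.tsv"),
              gene_model = p("gene_model.tsv"), gmt = p("sets.gmt"),
              footprints = p("footprints.tsv"),
              outdir = file.path(dir, "report"),
              conditions = as.list(setNames(sim$conditions,
                                            c("control", "acute",
                                              "chronic"))),
              seed = as.integer(seed))
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(dir)
}
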