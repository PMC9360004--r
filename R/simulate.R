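# Synthetic paired mRNA-seq / Ribo-seq data with planted ground truth.
#
# The generator emulates the structure of a chronic ER-stress profiling
# study: ~10^4 transcripts, three conditions (control, acute stress, chronic
# stress) x three replicates x two assays, negative-binomial counts
# (variance = mu + alpha * mu^2), planted temporal regulation classes for
# abundance and occupancy, and footprint records with 3-nt periodicity.
#
# Planted effect sizes are drawn so that every derived planted quantity
# (acute/chronic/overall L2DE per channel; x, y and x - y per contrast)
# keeps a margin of at least 0.3 from every classification boundary (0.32
# and 0.6); a transcript is therefore never planted "on the fence" and
# noise-free classification is unambiguous. A floor on the combined planted
# log2 change (>= -2.8 per condition) keeps expected counts well above the
# integer-discreteness floor; class combinations that cannot satisfy the
# floor (strong joint down-regulation of abundance and occupancy) are not
# co-planted.

TEMPORAL_PATTERNS <- c(up_up = 1, up_down = 2, none_up = 3, down_down = 4,
                       down_up = 5, none_down = 6)

ABUNDANCE_LABELS <- c(up_up = "G1", up_down = "G2", none_up = "G3",
                      down_down = "G4", down_up = "G5", none_down = "G6",
                      none = "none")
OCCUPANCY_LABELS <- c(up_up = "G7", up_down = "G8", none_up = "G9",
                      none_down = "G10", down_up = "G11", down_down = "G12",
                      none = "none")

# sign pattern (acute, chronic) per temporal pattern; 0 = no planted change
pattern_signs <- function(pattern) {
  switch(pattern,
         up_up = c(1, 1), up_down = c(1, -1), none_up = c(0, 1),
         down_down = c(-1, -1), down_up = c(-1, 1), none_down = c(0, -1),
         none = c(0, 0))
}

#' Generate a synthetic gene model
#'
#' Transcript lengths are uniform on 500-5000 nt; each CDS is a multiple of
#' 3 covering roughly 40-90% of the transcript with both UTRs at least 40
#' nt, so that P-site offsetting never pushes a CDS-internal footprint off
#' the transcript.
#'
#' @param n_genes Number of genes.
#' @param transcripts_per_gene Integer (constant) number of transcripts per
#'   gene, or a vector of length `n_genes`.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A validated gene-model tibble.
#' @export
generate_gene_model <- function(n_genes, transcripts_per_gene = 1L,
                                seed = 1L) {
  stopifnot(n_genes >= 1)
  set.seed(split_seed(seed, "gene_model"))
  tpg <- rep_len(transcripts_per_gene, n_genes)
  gene_id <- rep(sprintf("g%04d", seq_len(n_genes)), times = tpg)
  n_tx <- length(gene_id)
  len <- as.integer(floor(runif(n_tx, 500, 5001)))
  frac <- runif(n_tx, 0.4, 0.9)
  cds_len <- pmin(as.integer(floor(len * frac)), len - 80L)
  cds_len <- pmax(cds_len - (cds_len %% 3L), 60L)
  utr_total <- len - cds_len
  cds_start <- 40L + as.integer(floor(runif(n_tx) * (utr_total - 79L)))
  validate_gene_model(tibble(
    transcript_id = sprintf("tx%05d", seq_len(n_tx)),
    gene_id = gene_id,
    length = len,
    cds_start = cds_start,
    cds_end = cds_start + cds_len
  ))
}

# Draw effect magnitudes for one channel given its pattern, uniform on
# [0.9, 1.2] before margin rejection.
draw_magnitudes <- function(signs, n) {
  m1 <- runif(n, 0.9, 1.2) * signs[, 1]
  m2 <- runif(n, 0.9, 1.2) * signs[, 2]
  cbind(m1, m2)
}

margin_ok <- function(v, boundary, margin) {
  abs(abs(v) - boundary) >= margin
}

#' Plant ground-truth regulation classes and effect sizes
#'
#' Assigns each transcript a planted abundance class (G1-G6 or none) and
#' occupancy class (G7-G12 or none) with acute and chronic log2 effect
#' sizes, a baseline expression level and a baseline occupancy. Effect
#' magnitudes are redrawn (rejection sampling) until every planted derived
#' quantity keeps `margin` from the classification boundaries, and the
#' combined planted log2 change stays above the count floor.
#'
#' @param model Gene model (one truth row per transcript).
#' @param seed Integer seed.
#' @param prob_abundance,prob_occupancy Named class probabilities over
#'   `c("none", "G1".."G6")` / `c("none", "G7".."G12")`. Defaults emulate a
#'   chronic-stress study: changes concentrated in the chronic phase for
#'   abundance and in the acute phase for occupancy, ~20% of transcripts
#'   planted per channel.
#' @param margin Minimum distance of planted quantities from the 0.32 and
#'   0.6 boundaries (default 0.3).
#' @param floor_l2de Lower bound on the combined planted log2 change per
#'   condition (default -2.8).
#' @return A truth tibble: per transcript the baselines, class labels,
#'   effect sizes and the planted regulation mode per contrast.
#' @export
plant_truth <- function(model, seed = 1L,
                        prob_abundance = c(none = 0.80, G1 = 0.015,
                                           G2 = 0.015, G3 = 0.06,
                                           G4 = 0.015, G5 = 0.015,
                                           G6 = 0.08),
                        prob_occupancy = c(none = 0.80, G7 = 0.015,
                                           G8 = 0.06, G9 = 0.015,
                                           G10 = 0.06, G11 = 0.015,
                                           G12 = 0.035),
                        margin = 0.3, floor_l2de = -2.8) {
  set.seed(split_seed(seed, "truth"))
  n <- nrow(model)
  stopifnot(abs(sum(prob_abundance) - 1) < 1e-8,
            abs(sum(prob_occupancy) - 1) < 1e-8)

  baseline_rpkm <- pmin(pmax(rlnorm(n, meanlog = log(40), sdlog = 0.8),
                             10), 500)
  baseline_occ <- pmin(pmax(rlnorm(n, meanlog = 0, sdlog = 0.4), 0.5), 4)

  ab_class <- sample(names(prob_abundance), n, replace = TRUE,
                     prob = prob_abundance)
  ab_pattern <- names(ABUNDANCE_LABELS)[match(ab_class, ABUNDANCE_LABELS)]

  # occupancy class conditional on abundance: strong joint down-regulation
  # cannot satisfy the count floor and is not co-planted
  occ_pattern <- character(n)
  for (ab_p in unique(ab_pattern)) {
    idx <- which(ab_pattern == ab_p)
    p <- prob_occupancy
    forbidden <- switch(ab_p,
                        down_down = c("G12", "G10"),
                        none_down = "G12",
                        character(0))
    if (length(forbidden) > 0) {
      p[forbidden] <- 0
      p <- p / sum(p)
    }
    cls <- sample(names(p), length(idx), replace = TRUE, prob = p)
    occ_pattern[idx] <- names(OCCUPANCY_LABELS)[match(cls, OCCUPANCY_LABELS)]
  }
  occ_class <- unname(OCCUPANCY_LABELS[occ_pattern])

  ab_signs <- t(vapply(ab_pattern, pattern_signs, numeric(2)))
  occ_signs <- t(vapply(occ_pattern, pattern_signs, numeric(2)))

  ab_eff <- draw_magnitudes(ab_signs, n)
  occ_eff <- draw_magnitudes(occ_signs, n)

  needs_overall <- function(pattern) pattern %in% c("none_up", "none_down",
                                                    "none")
  ab_check_overall <- needs_overall(ab_pattern)
  occ_check_overall <- needs_overall(occ_pattern)

  bad_rows <- function(ab_eff, occ_eff, chk_a, chk_o) {
    a1 <- ab_eff[, 1]; a2 <- ab_eff[, 2]; a12 <- a1 + a2
    o1 <- occ_eff[, 1]; o2 <- occ_eff[, 2]; o12 <- o1 + o2
    ok <- margin_ok(a1, 0.32, margin) & margin_ok(a2, 0.32, margin) &
      (!chk_a | margin_ok(a12, 0.32, margin)) &
      margin_ok(o1, 0.32, margin) & margin_ok(o2, 0.32, margin) &
      (!chk_o | margin_ok(o12, 0.32, margin))
    for (xy in list(cbind(a1, o1), cbind(a2, o2), cbind(a12, o12))) {
      x <- xy[, 1]; y <- xy[, 1] + xy[, 2]
      ok <- ok & margin_ok(x, 0.6, margin) & margin_ok(y, 0.6, margin) &
        margin_ok(x - y, 0.6, margin)
    }
    ok <- ok & (a1 + o1 >= floor_l2de) & (a12 + o12 >= floor_l2de)
    !ok
  }

  bad <- bad_rows(ab_eff, occ_eff, ab_check_overall, occ_check_overall)
  iter <- 0
  while (any(bad)) {
    iter <- iter + 1
    if (iter > 200) {
      stop_tl("planted-effect rejection sampling did not converge")
    }
    idx <- which(bad)
    ab_eff[idx, ] <- draw_magnitudes(ab_signs[idx, , drop = FALSE],
                                     length(idx))
    occ_eff[idx, ] <- draw_magnitudes(occ_signs[idx, , drop = FALSE],
                                      length(idx))
    bad[idx] <- bad_rows(ab_eff[idx, , drop = FALSE],
                         occ_eff[idx, , drop = FALSE],
                         ab_check_overall[idx], occ_check_overall[idx])
  }

  truth <- tibble(
    transcript_id = model$transcript_id,
    gene_id = model$gene_id,
    baseline_rpkm = baseline_rpkm,
    baseline_occ = baseline_occ,
    abundance_group = ab_class,
    ab_acute = ab_eff[, 1], ab_chronic = ab_eff[, 2],
    occupancy_group = occ_class,
    occ_acute = occ_eff[, 1], occ_chronic = occ_eff[, 2]
  )
  truth |>
    mutate(
      mode_acute = classify_regulation_mode(
        .data$ab_acute, .data$ab_acute + .data$occ_acute),
      mode_chronic = classify_regulation_mode(
        .data$ab_chronic, .data$ab_chronic + .data$occ_chronic),
      mode_overall = classify_regulation_mode(
        .data$ab_acute + .data$ab_chronic,
        .data$ab_acute + .data$ab_chronic +
          .data$occ_acute + .data$occ_chronic)
    )
}

#' Generate negative-binomial count tables from a planted truth
#'
#' Expected mRNA RPKM at each condition is `baseline * 2^(cumulative
#' planted abundance L2DE)`; expected Ribo-seq RPKM multiplies in the
#' baseline occupancy and `2^(cumulative planted occupancy L2DE)`. Expected
#' counts follow from transcript length and the nominal library size, and
#' counts are drawn negative-binomially with `variance = mu + alpha mu^2`;
#' `alpha = 0` yields the rounded means exactly.
#'
#' @param truth Truth tibble from [plant_truth()].
#' @param model Gene model.
#' @param conditions Character vector of length 3: control, acute-stress
#'   and chronic-stress condition names.
#' @param n_replicates Replicates per condition per assay.
#' @param dispersion Named vector `c(mrna=, ribo=)` of NB dispersions alpha.
#' @param lib_size Named vector `c(mrna=, ribo=)` of nominal library sizes.
#' @param seed Integer seed.
#' @return A long count tibble covering both assays (see
#'   [read_count_table()] for the columns).
#' @export
generate_counts <- function(truth, model,
                            conditions = c("CON", "CPA1", "CPA18"),
                            n_replicates = 3,
                            dispersion = c(mrna = 0.05, ribo = 0.05),
                            lib_size = c(mrna = 2e7, ribo = 2e7),
                            seed = 1L) {
  stopifnot(length(conditions) == 3,
            all(c("mrna", "ribo") %in% names(dispersion)),
            all(c("mrna", "ribo") %in% names(lib_size)))
  set.seed(split_seed(seed, "counts"))
  len_kb <- model$length[match(truth$transcript_id,
                               model$transcript_id)] / 1000

  cum_ab <- cbind(0, truth$ab_acute, truth$ab_acute + truth$ab_chronic)
  cum_occ <- cbind(0, truth$occ_acute, truth$occ_acute + truth$occ_chronic)

  out <- vector("list", 2 * 3 * n_replicates)
  k <- 0
  for (assay in c("mrna", "ribo")) {
    alpha <- dispersion[[assay]]
    lib <- lib_size[[assay]]
    for (ci in seq_along(conditions)) {
      target_rpkm <- truth$baseline_rpkm * 2^cum_ab[, ci]
      if (assay == "ribo") {
        target_rpkm <- target_rpkm * truth$baseline_occ * 2^cum_occ[, ci]
      }
      mu <- target_rpkm * len_kb * lib / 1e6
      if (mean(mu < 1) > 0.5) {
        warn_tl("library size too small: expected count < 1 for >50%% of transcripts")
      }
      for (rep_i in seq_len(n_replicates)) {
        cnt <- if (alpha == 0) round(mu) else
          rnbinom(length(mu), mu = mu, size = 1 / alpha)
        k <- k + 1
        out[[k]] <- tibble(
          transcript_id = truth$transcript_id,
          sample_id = paste(assay, conditions[ci], rep_i, sep = "_"),
          assay = assay,
          condition = conditions[ci],
          replicate = as.integer(rep_i),
          count = as.numeric(cnt)
        )
      }
    }
  }
  validate_counts(bind_rows(out), model = model)
}

#' One-call synthetic experiment
#'
#' Generates a gene model, plants a ground truth and draws the paired
#' count tables. Defaults reproduce the structure of the emulated study:
#' 10,000 transcripts, 3 conditions x 3 replicates x 2 assays, NB
#' dispersion 0.05.
#'
#' @param n_transcripts Number of transcripts (one per gene).
#' @param seed Integer master seed; all stages split their own stream from
#'   it (see [split_seed()]).
#' @inheritParams generate_counts
#' @param ... Passed to [plant_truth()] (class probabilities, margin).
#' @return A list with `model`, `truth`, `counts` (long tibble, both
#'   assays) and the `conditions` used.
#' @export
simulate_experiment <- function(n_transcripts = 10000,
                                conditions = c("CON", "CPA1", "CPA18"),
                                n_replicates = 3,
                                dispersion = c(mrna = 0.05, ribo = 0.05),
                                lib_size = c(mrna = 2e7, ribo = 2e7),
                                seed = 1L, ...) {
  model <- generate_gene_model(n_transcripts, 1L, seed = seed)
  truth <- plant_truth(model, seed = seed, ...)
  counts <- generate_counts(truth, model, conditions = conditions,
                            n_replicates = n_replicates,
                            dispersion = dispersion, lib_size = lib_size,
                            seed = seed)
  list(model = model, truth = truth, counts = counts,
       conditions = conditions)
}

#' Generate synthetic footprint records
#'
#' Places reads on the transcripts of a gene model. With `region = "cds"`
#' (the Ribo-seq emulation) each read's P site falls inside the CDS, in
#' frame 0 with probability `frame0_fraction` and in frames 1/2 with equal
#' probability otherwise; read lengths are uniform on 26-32 nt. With
#' `region = "transcript"` (the mRNA-seq emulation) the 5' end is uniform
#' over the transcript and `frame0_fraction` is ignored.
#'
#' @param model Gene model.
#' @param n_reads Number of reads.
#' @param frame0_fraction Probability that a CDS read is in frame 0
#'   (1/3 = no periodicity).
#' @param p_site_offset Offset used to place the 5' end relative to the
#'   sampled P site (default 12).
#' @param seed Integer seed.
#' @param region `"cds"` or `"transcript"`.
#' @param transcripts Optional transcript ids to restrict to.
#' @return A footprint tibble (`transcript_id`, `five_prime_pos`, `length`).
#' @export
generate_footprints <- function(model, n_reads, frame0_fraction = 0.9,
                                p_site_offset = 12L, seed = 1L,
                                region = c("cds", "transcript"),
                                transcripts = NULL) {
  region <- match.arg(region)
  stopifnot(frame0_fraction >= 0, frame0_fraction <= 1)
  set.seed(split_seed(seed, paste0("footprints_", region)))
  model <- validate_gene_model(model)
  if (!is.null(transcripts)) {
    model <- model[model$transcript_id %in% transcripts, ]
  }
  n_codons <- (model$cds_end - model$cds_start) %/% 3L
  weights <- if (region == "cds") n_codons else model$length
  tx <- sample.int(nrow(model), n_reads, replace = TRUE,
                   prob = weights)
  read_len <- sample(26:32, n_reads, replace = TRUE)
  if (region == "cds") {
    frame <- ifelse(runif(n_reads) < frame0_fraction, 0L,
                    sample(1:2, n_reads, replace = TRUE))
    codon <- floor(runif(n_reads) * n_codons[tx])
    p_site <- model$cds_start[tx] + 3L * as.integer(codon) + frame
    five_prime <- p_site - as.integer(p_site_offset)
  } else {
    five_prime <- as.integer(floor(runif(n_reads) *
                                     (model$length[tx] - read_len + 1L)))
  }
  tibble(transcript_id = model$transcript_id[tx],
         five_prime_pos = as.integer(five_prime),
         length = as.integer(read_len))
}

#' Generate a two-group cohort expression matrix with planted shifts
#'
#' Log-normal expression for `n_genes` genes in two groups; the genes in
#' `shifted_genes` differ by `log2_shift` (in log2 units) in the second
#' group. Emulates the disease-vs-control comparison inputs for
#' [compare_geneset_expression()].
#'
#' @param n_genes Number of genes (ids `gene1..geneN`).
#' @param n_per_group Samples per group.
#' @param shifted_genes Character vector of gene ids to shift.
#' @param log2_shift Planted shift (log2 units; negative = down in group 2).
#' @param sdlog2 Biological spread per gene in log2 units (default 0.5).
#' @param seed Integer seed.
#' @param group_labels Labels for the two groups (reference first).
#' @return A list with `expr` (long tibble `gene_id`, `sample_id`,
#'   `value`), `groups` (sample-to-group tibble) and `truth`.
#' @export
generate_cohort_expression <- function(n_genes, n_per_group,
                                       shifted_genes = character(),
                                       log2_shift = 0, sdlog2 = 0.5,
                                       seed = 1L,
                                       group_labels = c("CON", "T1D")) {
  set.seed(split_seed(seed, "cohort"))
  genes <- sprintf("gene%d", seq_len(n_genes))
  stopifnot(all(shifted_genes %in% genes))
  samples <- tibble(
    sample_id = sprintf("s%03d", seq_len(2 * n_per_group)),
    group = factor(rep(group_labels, each = n_per_group),
                   levels = group_labels)
  )
  base_log2 <- rnorm(n_genes, mean = log2(100), sd = 1)
  expr <- tidyr::crossing(gene_id = genes, sample_id = samples$sample_id) |>
    left_join(samples, by = "sample_id") |>
    mutate(
      mu_log2 = base_log2[match(.data$gene_id, genes)] +
        ifelse(.data$gene_id %in% shifted_genes &
                 .data$group == group_labels[2], log2_shift, 0),
      value = 2^(.data$mu_log2 + rnorm(dplyr::n(), 0, sdlog2))
    ) |>
    select("gene_id", "sample_id", "value")
  list(expr = expr,
       groups = select(samples, "sample_id", "group"),
       truth = tibble(gene_id = genes,
                      shifted = genes %in% shifted_genes,
                      log2_shift = ifelse(genes %in% shifted_genes,
                                          log2_shift, 0)))
}
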