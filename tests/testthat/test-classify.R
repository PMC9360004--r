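test_that("l2de is the log2 ratio and rejects non-positive input", {
  expect_equal(l2de(4, 1), 2)
  expect_equal(l2de(7.3, 7.3), 0)
  expect_equal(l2de(3, 2), log2(1.5))
  expect_error(l2de(0, 1), "positive")
  expect_error(l2de(1, -2), "positive")
  expect_error(l2de(NaN, 1), "positive")
})

test_that("temporal abundance rules reproduce worked examples", {
  expect_equal(classify_temporal_abundance(0.5, 0.5, 1.0), "G1")
  expect_equal(classify_temporal_abundance(0.5, -0.5, 0.0), "G2")
  expect_equal(classify_temporal_abundance(0.0, 0.7, 0.7), "G3")
  expect_equal(classify_temporal_abundance(-0.5, -0.5, -1.0), "G4")
  expect_equal(classify_temporal_abundance(-0.5, 0.8, 0.3), "G5")
  expect_equal(classify_temporal_abundance(0.0, -0.7, -0.7), "G6")
  expect_equal(classify_temporal_abundance(0.1, 0.1, 0.2), "none")
  # G3 needs the overall contrast to agree
  expect_equal(classify_temporal_abundance(0.0, 0.7, 0.1), "none")
})

test_that("temporal occupancy rules use the G7-G12 code order", {
  expect_equal(classify_temporal_occupancy(0.4, 0.4, 0.8), "G7")
  expect_equal(classify_temporal_occupancy(0.4, -0.5, -0.1), "G8")
  expect_equal(classify_temporal_occupancy(0.0, 0.4, 0.4), "G9")
  expect_equal(classify_temporal_occupancy(0.0, -0.4, -0.4), "G10")
  expect_equal(classify_temporal_occupancy(-0.4, 0.5, 0.1), "G11")
  expect_equal(classify_temporal_occupancy(-0.4, -0.4, -0.8), "G12")
})

test_that("boundary values behave exactly as specified", {
  # 0.32 itself is "up" (inclusive)
  expect_equal(classify_temporal_abundance(0.32, 0.32, 0.64), "G1")
  expect_equal(classify_temporal_abundance(-0.32, -0.32, -0.64), "G4")
  # just inside the band is "no change"
  expect_equal(classify_temporal_abundance(0.3199, 0.32, 0.32), "G3")
  # x - y = -0.6 is inside the band (inclusive), +0.6 outside (strict)
  expect_equal(classify_regulation_mode(0.6, 1.2), "up_both")
  expect_equal(classify_regulation_mode(1.2, 0.6), "none")
  expect_equal(classify_regulation_mode(1.1, 0.61), "up_both")
  # y = cutoff exactly: up_occ_only needs strict y > 0.6
  expect_equal(classify_regulation_mode(-0.2, 0.6), "none")
  expect_equal(classify_regulation_mode(-0.2, 0.601), "up_occ_only")
})

test_that("regulation mode reproduces worked examples", {
  expect_equal(classify_regulation_mode(1.0, 0.8), "up_both")
  expect_equal(classify_regulation_mode(0.0, 1.0), "up_occ_only")
  expect_equal(classify_regulation_mode(-1.0, -0.8), "down_both")
  expect_equal(classify_regulation_mode(0.0, -1.0), "down_occ_only")
  expect_equal(classify_regulation_mode(0.5, 0.5), "none")
})

test_that("each rule family forms a partition on a dense grid", {
  g <- seq(-2, 2, by = 0.01)
  grid <- tidyr::crossing(acute = g, chronic = g,
                          overall = c(-1, -0.32, -0.31, 0, 0.31, 0.32, 1))
  c0 <- 0.32
  rules <- list(
    G1 = grid$acute >= c0 & grid$chronic >= c0,
    G2 = grid$acute >= c0 & grid$chronic <= -c0,
    G3 = abs(grid$acute) < c0 & grid$chronic >= c0 & grid$overall >= c0,
    G4 = grid$acute <= -c0 & grid$chronic <= -c0,
    G5 = grid$acute <= -c0 & grid$chronic >= c0,
    G6 = abs(grid$acute) < c0 & grid$chronic <= -c0 & grid$overall <= -c0
  )
  n_match <- Reduce(`+`, lapply(rules, as.integer))
  expect_true(all(n_match <= 1))

  # the classifier agrees with the single matching rule everywhere
  lab <- classify_temporal_abundance(grid$acute, grid$chronic, grid$overall)
  for (gname in names(rules)) {
    expect_true(all(lab[rules[[gname]]] == gname))
  }
  expect_true(all(lab[n_match == 0] == "none"))

  # regulation modes partition the (x, y) plane
  xy <- tidyr::crossing(x = g, y = g)
  c1 <- 0.6
  d <- xy$x - xy$y
  mrules <- list(
    up_both = d >= -c1 & d < c1 & xy$x >= c1 & xy$y >= c1,
    up_occ_only = d < -c1 & xy$y > c1,
    down_both = d >= -c1 & d < c1 & xy$x <= -c1 & xy$y <= -c1,
    down_occ_only = d > c1 & xy$y < -c1
  )
  m_match <- Reduce(`+`, lapply(mrules, as.integer))
  expect_true(all(m_match <= 1))
  mlab <- classify_regulation_mode(xy$x, xy$y)
  for (mname in names(mrules)) {
    expect_true(all(mlab[mrules[[mname]]] == mname))
  }
  expect_true(all(mlab[m_match == 0] == "none"))
})

test_that("vectorized classifiers agree with the naive scalar evaluator", {
  set.seed(20)
  n <- 50000
  a <- runif(n, -2, 2); c_ <- runif(n, -2, 2); o <- runif(n, -2, 2)
  expect_equal(classify_temporal_abundance(a, c_, o),
               mapply(naive_abundance, a, c_, o, USE.NAMES = FALSE))
  expect_equal(classify_temporal_occupancy(a, c_, o),
               mapply(naive_occupancy, a, c_, o, USE.NAMES = FALSE))
  x <- runif(n, -2, 2); y <- runif(n, -2, 2)
  expect_equal(classify_regulation_mode(x, y),
               mapply(naive_mode, x, y, USE.NAMES = FALSE))
})

test_that("classify_dataset recovers a planted noise-free pattern", {
  meta <- standard_meta()
  n_tx <- 30
  ids <- sprintf("tx%02d", seq_len(n_tx))
  base <- 100
  mat <- matrix(base, nrow = n_tx, ncol = nrow(meta),
                dimnames = list(ids, meta$sample_id))
  # transcripts 1-10: abundance +1 acute, +1 chronic in both assays -> G1
  up <- ids[1:10]
  for (s in meta$sample_id[meta$condition == "CPA1"]) mat[up, s] <- base * 2
  for (s in meta$sample_id[meta$condition == "CPA18"]) mat[up, s] <- base * 4
  # ballast row keeps per-sample totals identical so RPKM ratios equal
  # count ratios exactly
  ballast <- "tx30"
  for (s in meta$sample_id) {
    mat[ballast, s] <- 13000 - sum(mat[ids[ids != ballast], s])
  }
  fx_model <- tibble::tibble(transcript_id = ids,
                             gene_id = paste0("g", seq_len(n_tx)),
                             length = 1000L, cds_start = 0L,
                             cds_end = 300L)
  counts <- counts_from_matrix(mat, meta)
  rpkm <- compute_rpkm(counts, fx_model)
  det <- detected_transcripts(rpkm)
  occ <- compute_occupancy(rpkm, det)
  cls <- classify_dataset(rpkm, occ)

  g <- cls$groups
  expect_setequal(g$abundance_group[g$transcript_id %in% up], "G1")
  expect_equal(cls$summary$n[cls$summary$channel == "abundance" &
                               cls$summary$group == "G1"], 10)
  # both assays shifted equally: occupancy unchanged -> no G7-G12 calls
  expect_setequal(g$occupancy_group, "none")
  # and the summary marginals account for every transcript
  expect_equal(sum(cls$summary$n[cls$summary$channel == "abundance"]),
               n_tx)
})

test_that("all-identical conditions yield no classification", {
  meta <- standard_meta()
  ids <- sprintf("tx%02d", 1:5)
  mat <- matrix(rep(c(50, 80, 120, 60, 90), nrow(meta)), nrow = 5,
                dimnames = list(ids, meta$sample_id))
  model <- tibble::tibble(transcript_id = ids, gene_id = ids,
                          length = 1000L, cds_start = 0L, cds_end = 300L)
  counts <- counts_from_matrix(mat, meta)
  rpkm <- compute_rpkm(counts, model)
  occ <- compute_occupancy(rpkm, detected_transcripts(rpkm))
  cls <- classify_dataset(rpkm, occ)
  expect_setequal(cls$groups$abundance_group, "none")
  expect_setequal(cls$groups$occupancy_group, "none")
  expect_setequal(cls$modes$mode, "none")
  expect_equal(max(abs(cls$l2de$x)), 0)
})

test_that("occupancy L2DE equals y - x to numerical precision", {
  sim <- simulate_experiment(n_transcripts = 200,
                             dispersion = c(mrna = 0.05, ribo = 0.05),
                             seed = 9)
  rpkm <- compute_rpkm(sim$counts, sim$model)
  occ <- compute_occupancy(rpkm, detected_transcripts(rpkm))
  cls <- classify_dataset(rpkm, occ)
  expect_lt(max(abs(cls$l2de$occ_l2de - (cls$l2de$y - cls$l2de$x))), 1e-9)
})

test_that("classify_dataset matches per-transcript scalar classification", {
  sim <- simulate_experiment(n_transcripts = 150,
                             dispersion = c(mrna = 0.1, ribo = 0.1),
                             seed = 13)
  rpkm <- compute_rpkm(sim$counts, sim$model)
  occ <- compute_occupancy(rpkm, detected_transcripts(rpkm))
  cls <- classify_dataset(rpkm, occ)
  wide <- tidyr::pivot_wider(cls$l2de[, c("transcript_id", "contrast",
                                          "x", "occ_l2de")],
                             names_from = "contrast",
                             values_from = c("x", "occ_l2de"))
  for (i in seq_len(nrow(wide))) {
    expect_equal(
      cls$groups$abundance_group[cls$groups$transcript_id ==
                                   wide$transcript_id[i]],
      naive_abundance(wide$x_acute[i], wide$x_chronic[i],
                      wide$x_overall[i]))
    expect_equal(
      cls$groups$occupancy_group[cls$groups$transcript_id ==
                                   wide$transcript_id[i]],
      naive_occupancy(wide$occ_l2de_acute[i], wide$occ_l2de_chronic[i],
                      wide$occ_l2de_overall[i]))
  }
})

test_that("classify_dataset rejects a contrast over unknown conditions", {
  sim <- simulate_experiment(n_transcripts = 50,
                             dispersion = c(mrna = 0, ribo = 0), seed = 2)
  rpkm <- compute_rpkm(sim$counts, sim$model)
  occ <- compute_occupancy(rpkm, detected_transcripts(rpkm))
  expect_error(
    classify_dataset(rpkm, occ,
                     conditions = c(control = "CON", acute = "CPA1",
                                    chronic = "CPA99")),
    "absent")
})

test_that("tidy and glance summarise a classification", {
  sim <- simulate_experiment(n_transcripts = 100,
                             dispersion = c(mrna = 0, ribo = 0), seed = 4)
  rpkm <- compute_rpkm(sim$counts, sim$model)
  occ <- compute_occupancy(rpkm, detected_transcripts(rpkm))
  cls <- classify_dataset(rpkm, occ)
  td <- generics::tidy(cls)
  expect_equal(nrow(td), 3 * cls$params$n_transcripts)
  expect_true(all(c("x", "y", "occ_l2de", "abundance_group", "mode") %in%
                    names(td)))
  gl <- generics::glance(cls)
  expect_equal(gl$n_transcripts, 100)
})
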