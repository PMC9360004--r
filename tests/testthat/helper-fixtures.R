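# Shared fixture builders and independent oracles.

tiny_model <- function() {
  tibble::tibble(
    transcript_id = c("tx1", "tx2", "tx3"),
    gene_id = c("g1", "g2", "g2"),
    length = c(2000L, 1000L, 500L),
    cds_start = c(100L, 60L, 45L),
    cds_end = c(1600L, 960L, 405L)
  )
}

# build a long count tibble from a transcripts x samples matrix
counts_from_matrix <- function(mat, meta) {
  tibble::as_tibble(mat, rownames = "transcript_id") |>
    tidyr::pivot_longer(-transcript_id, names_to = "sample_id",
                        values_to = "count") |>
    dplyr::inner_join(meta, by = "sample_id") |>
    dplyr::select(transcript_id, sample_id, assay, condition, replicate,
                  count)
}

standard_meta <- function(conditions = c("CON", "CPA1", "CPA18"),
                          n_rep = 3) {
  tidyr::crossing(assay = c("mrna", "ribo"), condition = conditions,
                  replicate = seq_len(n_rep)) |>
    dplyr::mutate(sample_id = paste(assay, condition, replicate, sep = "_"),
                  condition = factor(condition, levels = conditions)) |>
    dplyr::arrange(assay, condition, replicate) |>
    dplyr::mutate(condition = as.character(condition),
                  replicate = as.integer(replicate)) |>
    dplyr::select(sample_id, assay, condition, replicate)
}

# Naive scalar rule evaluators, coded independently of the vectorized
# production classifiers (nested if/else, one value at a time).
naive_temporal <- function(acute, chronic, overall, cutoff, labels) {
  if (acute >= cutoff) {
    if (chronic >= cutoff) return(labels[1])
    if (chronic <= -cutoff) return(labels[2])
    return("none")
  }
  if (acute <= -cutoff) {
    if (chronic <= -cutoff) return(labels[4])
    if (chronic >= cutoff) return(labels[5])
    return("none")
  }
  # |acute| < cutoff
  if (chronic >= cutoff && overall >= cutoff) return(labels[3])
  if (chronic <= -cutoff && overall <= -cutoff) return(labels[6])
  "none"
}

naive_abundance <- function(a, c, o, cutoff = 0.32) {
  naive_temporal(a, c, o, cutoff, paste0("G", 1:6))
}

# occupancy label order: up/up, up/down, none/up, none/down, down/up,
# down/down
naive_occupancy <- function(a, c, o, cutoff = 0.32) {
  naive_temporal(a, c, o, cutoff,
                 c("G7", "G8", "G9", "G12", "G11", "G10"))
}

naive_mode <- function(x, y, cutoff = 0.6) {
  d <- x - y
  if (d >= -cutoff && d < cutoff && x >= cutoff && y >= cutoff) {
    return("up_both")
  }
  if (d < -cutoff && y > cutoff) return("up_occ_only")
  if (d >= -cutoff && d < cutoff && x <= -cutoff && y <= -cutoff) {
    return("down_both")
  }
  if (d > cutoff && y < -cutoff) return("down_occ_only")
  "none"
}

# brute-force RPKM, cell by cell
naive_rpkm <- function(count, length_nt, total) {
  count / (length_nt / 1000) / (total / 1e6)
}

# exhaustive hypergeometric upper tail by subset enumeration:
# draw n from a universe of N with K marked; P(overlap >= k)
enumerate_hyper_p <- function(N, K, n, k) {
  universe <- seq_len(N)
  marked <- universe <= K
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(marked[draws], nrow = n))
  mean(hits >= k)
}

# reference BH step-up: largest j with p_(j) <= j/m * alpha is the cut
reference_bh_flags <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) / m * alpha)
  flags <- logical(m)
  if (length(below) > 0) flags[ord[seq_len(max(below))]] <- TRUE
  flags
}
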