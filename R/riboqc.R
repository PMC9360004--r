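# Ribo-seq quality control: reading-frame periodicity and CDS enrichment.
#
# Footprint 5' ends are offset to the ribosomal P site before frame
# assignment. The default offset of +12 nt is the standard for ~28-nt
# footprints; it is a parameter (optionally length-stratified) because
# library protocols differ and the offset is a property of the protocol,
# not of the analysis.

p_site_positions <- function(reads, p_site_offset) {
  if (is.function(p_site_offset)) {
    reads$five_prime_pos + p_site_offset(reads$length)
  } else {
    reads$five_prime_pos + p_site_offset
  }
}

#' Reading-frame distribution of ribosome footprints
#'
#' Offsets every footprint 5' end to its P site, keeps reads whose P site
#' falls inside an annotated CDS (`[cds_start, cds_end)`), and tabulates
#' the P-site frame relative to the CDS start: `frame = (p_site -
#' cds_start) mod 3`. Active translation shows strong enrichment of frame
#' 0 (3-nt periodicity); a flat (1/3, 1/3, 1/3) profile indicates
#' non-ribosomal signal.
#'
#' @param reads Footprint tibble (`transcript_id`, `five_prime_pos`,
#'   `length`), e.g. from [read_footprints()].
#' @param model Gene model with CDS annotation.
#' @param p_site_offset Integer offset from the 5' end to the P site
#'   (default 12), or a function of read length returning the offset.
#' @return A one-row tibble of class `frame_distribution`: `f0`, `f1`,
#'   `f2` (fractions, `NA` when no read is counted), `n_reads` counted,
#'   `n_excluded` (reads outside any CDS or on unannotated transcripts).
#' @export
frame_distribution <- function(reads, model, p_site_offset = 12L) {
  assert_cols(reads, c("transcript_id", "five_prime_pos", "length"),
              "footprints")
  model <- validate_gene_model(model)
  dat <- inner_join(reads,
                    model[, c("transcript_id", "cds_start", "cds_end")],
                    by = "transcript_id")
  n_unannotated <- nrow(reads) - nrow(dat)
  p_site <- p_site_positions(dat, p_site_offset)
  in_cds <- p_site >= dat$cds_start & p_site < dat$cds_end
  frames <- (p_site[in_cds] - dat$cds_start[in_cds]) %% 3
  n <- length(frames)
  counts <- tabulate(frames + 1L, nbins = 3L)
  out <- tibble(
    f0 = if (n > 0) counts[1] / n else NA_real_,
    f1 = if (n > 0) counts[2] / n else NA_real_,
    f2 = if (n > 0) counts[3] / n else NA_real_,
    n_reads = n,
    n_excluded = n_unannotated + sum(!in_cds)
  )
  if (n == 0) warn_tl("no footprint P-site inside any CDS")
  structure(out, p_site_offset = p_site_offset,
            class = c("frame_distribution", class(out)))
}

#' CDS enrichment of Ribo-seq relative to mRNA-seq on one transcript
#'
#' For a single transcript, computes the fraction of Ribo-seq reads whose
#' P site lies inside the CDS and the fraction of mRNA-seq reads whose 5'
#' end does, and their ratio. Ribosome footprints concentrate on the
#' coding region while mRNA-seq reads cover the whole transcript, so a
#' ratio well above 1 (approaching `transcript_length / cds_length` for
#' uniform mRNA coverage) is the expected signature on a well-translated
#' transcript.
#'
#' @param ribo_reads,mrna_reads Footprint-style tibbles for the two assays.
#' @param model Gene model.
#' @param transcript_id Transcript to assess.
#' @param p_site_offset Offset applied to Ribo-seq reads only.
#' @return A one-row tibble: `transcript_id`, `ribo_cds_fraction`,
#'   `mrna_cds_fraction`, `ratio` (`NA` with a warning when there are no
#'   mRNA reads on the transcript or the mRNA fraction is zero).
#' @export
cds_enrichment <- function(ribo_reads, mrna_reads, model, transcript_id,
                           p_site_offset = 12L) {
  model <- validate_gene_model(model)
  row <- model[model$transcript_id == transcript_id, ]
  if (nrow(row) != 1) stop_tl("transcript %s not in gene model",
                              transcript_id)
  rr <- ribo_reads[ribo_reads$transcript_id == transcript_id, ]
  mr <- mrna_reads[mrna_reads$transcript_id == transcript_id, ]
  if (nrow(rr) == 0) stop_tl("no Ribo-seq reads on %s", transcript_id)
  frac_in_cds <- function(pos) {
    mean(pos >= row$cds_start & pos < row$cds_end)
  }
  ribo_frac <- frac_in_cds(p_site_positions(rr, p_site_offset))
  if (nrow(mr) == 0) {
    warn_tl("no mRNA-seq reads on %s; ratio undefined", transcript_id)
    mrna_frac <- NA_real_
  } else {
    mrna_frac <- frac_in_cds(mr$five_prime_pos)
    if (mrna_frac == 0) {
      warn_tl("mRNA CDS fraction is zero on %s; ratio undefined",
              transcript_id)
    }
  }
  tibble(transcript_id = transcript_id,
         ribo_cds_fraction = ribo_frac,
         mrna_cds_fraction = mrna_frac,
         ratio = if (!is.na(mrna_frac) && mrna_frac > 0)
           ribo_frac / mrna_frac else NA_real_)
}
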