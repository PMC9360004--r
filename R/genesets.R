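# Derivation of cell-type-specific stress gene sets and set-level statistics.

#' Derive a cell-type-specific gene set by reference exclusion
#'
#' Starts from the genes affected in the target cell type and removes every
#' gene that behaved similarly in a reference cell type, where "similarly"
#' means: changed in the same direction, in any channel (abundance or
#' occupancy), passing the same cutoff. A gene changed in *opposite*
#' directions in target and reference is retained. This is the construction
#' behind a chronic-stress "regulome": the stress response that is specific
#' to the target cell type.
#'
#' @param changes_target,changes_reference Tibbles of per-gene change calls
#'   with columns `gene_id`, `direction` (`"up"`/`"down"`), `channel`
#'   (`"abundance"`/`"occupancy"`) and `contrast`.
#' @param name Name recorded for the derived set.
#' @return A tibble of the retained target change records (columns as in
#'   `changes_target`), with attributes `set_name` and `excluded` (the
#'   gene ids removed by the reference filter).
#' @examples
#' target <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
#'   direction = c("up", "down", "up"),
#'   channel = "abundance", contrast = "overall")
#' ref <- target[1, ]
#' derive_cell_specific_set(target, ref)$gene_id  # gB, gC
#' @export
derive_cell_specific_set <- function(changes_target, changes_reference,
                                     name = "cell_specific") {
  cols <- c("gene_id", "direction", "channel", "contrast")
  assert_cols(changes_target, cols, "target changes")
  assert_cols(changes_reference, cols, "reference changes")
  if (nrow(changes_target) == 0) {
    warn_tl("empty target change list; derived set is empty")
  }
  bad_dir <- setdiff(unique(c(changes_target$direction,
                              changes_reference$direction)), c("up", "down"))
  if (length(bad_dir) > 0) stop_tl("direction must be up/down")
  excluded <- changes_target |>
    distinct(.data$gene_id, .data$direction) |>
    semi_join(distinct(changes_reference, .data$gene_id, .data$direction),
              by = c("gene_id", "direction")) |>
    pull("gene_id") |>
    unique()
  members <- changes_target |>
    filter(!.data$gene_id %in% excluded) |>
    as_tibble()
  structure(members, set_name = name, excluded = excluded,
            class = c("derived_geneset", class(members)))
}

#' Derive an adaptome: pathway genes upregulated under chronic stress
#'
#' The adaptome of a pathway is the subset of its genes that is upregulated
#' during chronic stress adaptation in either channel — increased mRNA
#' abundance or increased ribosome occupancy — split by whether each member
#' was also stress-regulated in a reference cell type. The reference-overlap
#' complement is the cell-type-specific part of the adaptome.
#'
#' @param up_abundance Character vector of genes with increased abundance.
#' @param up_occupancy Character vector of genes with translational
#'   (occupancy) upregulation.
#' @param pathway Character vector: the pathway gene set (e.g. ER protein
#'   processing).
#' @param reference_regulated Character vector of genes regulated in the
#'   reference cell type.
#' @param name Name recorded for the derived set.
#' @return A tibble with one row per member: `gene_id`, `source`
#'   (`"abundance"`, `"occupancy"` or `"both"`) and `in_reference`
#'   (shared with the reference cell type). Attribute `set_name` carries
#'   the name; `specific` members are the rows with `in_reference = FALSE`.
#' @export
derive_adaptome <- function(up_abundance, up_occupancy, pathway,
                            reference_regulated = character(),
                            name = "adaptome") {
  up_abundance <- unique(up_abundance)
  up_occupancy <- unique(up_occupancy)
  members <- intersect(union(up_abundance, up_occupancy), unique(pathway))
  out <- tibble(
    gene_id = members,
    source = dplyr::case_when(
      members %in% up_abundance & members %in% up_occupancy ~ "both",
      members %in% up_abundance ~ "abundance",
      .default = "occupancy"
    ),
    in_reference = members %in% reference_regulated
  )
  structure(out, set_name = name,
            class = c("derived_geneset", class(out)))
}

#' @export
print.derived_geneset <- function(x, ...) {
  if (!"gene_id" %in% names(x)) return(NextMethod())
  cat("Derived gene set", shQuote(attr(x, "set_name")), "with",
      n_distinct(x$gene_id), "member genes\n")
  if (!is.null(attr(x, "excluded"))) {
    cat("  excluded by reference filter:", length(attr(x, "excluded")),
        "genes\n")
  }
  if ("in_reference" %in% names(x)) {
    cat("  shared with reference:", sum(x$in_reference),
        "| specific:", sum(!x$in_reference), "\n")
  }
  NextMethod()
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test of whether a hit list is
#' enriched for a pathway within a gene universe:
#' `p = P(X >= overlap)` with `X ~ Hypergeometric(N = |universe|,
#' K = |pathway int universe|, n = |hits|)`. This is the generic
#' over-representation computation that annotation services perform per
#' pathway.
#'
#' @param hits Character vector of selected genes; must be a subset of
#'   `universe`.
#' @param universe Character vector: the detected gene universe.
#' @param pathway Character vector: the pathway gene set (intersected with
#'   the universe before testing).
#' @return A one-row tibble: `overlap`, `n_hits`, `n_pathway` (in-universe
#'   pathway size), `n_universe`, `p_value`.
#' @export
hypergeometric_enrichment <- function(hits, universe, pathway) {
  hits <- unique(hits); universe <- unique(universe)
  if (!all(hits %in% universe)) {
    stop_tl("hits must be a subset of the universe")
  }
  K <- length(intersect(unique(pathway), universe))
  N <- length(universe)
  n <- length(hits)
  overlap <- length(intersect(hits, pathway))
  p <- stats::phyper(overlap - 1, K, N - K, n, lower.tail = FALSE)
  tibble(overlap = overlap, n_hits = n, n_pathway = K, n_universe = N,
         p_value = p)
}

#' Over-representation of a hit list across a gene-set collection
#'
#' Applies [hypergeometric_enrichment()] to every set of a collection and
#' adjusts the p-values with Benjamini-Hochberg.
#'
#' @param hits,universe As in [hypergeometric_enrichment()].
#' @param sets Long gene-set tibble from [read_gmt()] (`set_name`,
#'   `gene_id`, optionally `description`).
#' @return A tibble with one row per set, ordered by p-value, with an added
#'   `fdr` column.
#' @export
enrich_genesets <- function(hits, universe, sets) {
  assert_cols(sets, c("set_name", "gene_id"), "gene-set collection")
  out <- sets |>
    group_by(.data$set_name) |>
    group_modify(~ hypergeometric_enrichment(hits, universe, .x$gene_id)) |>
    ungroup() |>
    mutate(fdr = stats::p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value)
  out
}

#' Compare gene-set expression between two cohorts
#'
#' Per-gene two-sided Wilcoxon-Mann-Whitney test between two sample groups
#' (e.g. healthy donors vs disease), with Benjamini-Hochberg adjustment
#' across the tested genes and a stringent default significance cutoff of
#' FDR <= 1e-3. The exact null distribution is used when both groups have
#' at most 20 samples and no ties; otherwise the normal approximation with
#' tie correction. Genes of the set absent from the expression table are
#' reported as untested rather than raising an error.
#'
#' @param expr Long expression tibble with columns `gene_id`, `sample_id`,
#'   `value` (any monotone expression unit; the test is rank-based).
#' @param groups Tibble with columns `sample_id`, `group`; exactly two
#'   group labels with at least two samples each. The first level (factor
#'   order, else sort order) is the reference group.
#' @param genes Character vector: the gene set to test.
#' @param fdr_cutoff Significance threshold on BH-adjusted p (default 1e-3).
#' @return An object of class `cohort_comparison`: a tibble with one row
#'   per requested gene — group means, `statistic`, `p_value`, `fdr`,
#'   `direction` (`"up"`/`"down"` in the non-reference group), `significant`
#'   and `tested` — with the group labels and cutoff as attributes.
#'   Supports [ggplot2::autoplot()] (volcano plot).
#' @export
compare_geneset_expression <- function(expr, groups, genes,
                                       fdr_cutoff = 1e-3) {
  assert_cols(expr, c("gene_id", "sample_id", "value"), "expression")
  assert_cols(groups, c("sample_id", "group"), "groups")
  lev <- if (is.factor(groups$group)) levels(droplevels(groups$group)) else
    sort(unique(as.character(groups$group)))
  if (length(lev) != 2) stop_tl("exactly two group labels required")
  groups <- mutate(groups, group = as.character(.data$group))
  n_per <- count(groups, .data$group)
  if (any(n_per$n < 2)) stop_tl("each group needs at least 2 samples")
  dat <- expr |>
    inner_join(groups, by = "sample_id") |>
    filter(.data$gene_id %in% genes)

  test_one <- function(d) {
    a <- d$value[d$group == lev[1]]
    b <- d$value[d$group == lev[2]]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(mean_ref = NA_real_, mean_alt = NA_real_,
                    statistic = NA_real_, p_value = NA_real_,
                    tested = FALSE))
    }
    exact <- length(a) <= 20 && length(b) <= 20 &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      stats::wilcox.test(b, a, alternative = "two.sided", exact = exact,
                         correct = TRUE)
    )
    tibble(mean_ref = mean(a), mean_alt = mean(b),
           statistic = unname(wt$statistic), p_value = wt$p.value,
           tested = TRUE)
  }

  res <- tibble(gene_id = unique(genes)) |>
    left_join(
      dat |> group_by(.data$gene_id) |> group_modify(~ test_one(.x)) |>
        ungroup(),
      by = "gene_id"
    ) |>
    mutate(tested = !is.na(.data$tested) & .data$tested)
  res$fdr <- NA_real_
  res$fdr[res$tested] <- stats::p.adjust(res$p_value[res$tested],
                                         method = "BH")
  res <- res |>
    mutate(direction = dplyr::case_when(
      !.data$tested ~ NA_character_,
      .data$mean_alt >= .data$mean_ref ~ "up",
      .default = "down"
    ),
    significant = .data$tested & .data$fdr <= fdr_cutoff)
  structure(res, groups = lev, fdr_cutoff = fdr_cutoff,
            class = c("cohort_comparison", class(res)))
}

#' @export
print.cohort_comparison <- function(x, ...) {
  lev <- attr(x, "groups")
  if (!is.null(lev) && all(c("tested", "significant") %in% names(x))) {
    cat("Cohort comparison", lev[2], "vs", lev[1], "-", sum(x$tested),
        "genes tested,", sum(x$significant), "significant at FDR <=",
        format(attr(x, "fdr_cutoff")), "\n")
  }
  NextMethod()
}

#' Venn partition of named gene sets
#'
#' Counts every region of the Venn partition of two or more named sets
#' (e.g. repressed genes called on two platforms) and lists the members of
#' each region.
#'
#' @param sets Named list of character vectors; at least two sets.
#' @return A tibble with one row per non-empty membership pattern plus the
#'   empty regions: `region` (set names joined by `&`), `sets` (number of
#'   sets in the pattern), `n`, and a `genes` list-column.
#' @examples
#' intersect_platforms(list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4")))
#' @export
intersect_platforms <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)) || any(names(sets) == "")) {
    stop_tl("need >= 2 named sets")
  }
  sets <- purrr::map(sets, unique)
  all_genes <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, names(sets)))
  # enumerate all 2^k - 1 patterns so empty regions are reported as n = 0
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  names(patterns) <- names(sets)
  purrr::map_dfr(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, ])
    in_region <- rowSums(membership == matrix(pat, nrow = nrow(membership),
                                              ncol = k, byrow = TRUE)) == k
    tibble(region = paste(names(sets)[pat], collapse = " & "),
           sets = sum(pat), n = sum(in_region),
           genes = list(rownames(membership)[in_region]))
  }) |>
    arrange(desc(.data$sets), .data$region)
}
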