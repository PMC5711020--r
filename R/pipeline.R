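#' End-to-end sequential dissection of a congenic panel
#'
#' Convenience driver chaining the full pipeline: genotype imputation,
#' phenotype preparation, per-strain donor-region summaries, strain
#' selection (narrow criterion), MST construction over full-length donor
#' regions, ordered LSD comparisons, and minimal multi-QTL model inference.
#'
#' @param panel a raw [congenic_panel()].
#' @param min_n per-genotype minimum group size for inclusion (default 12).
#' @param alpha LSD significance level (default 0.05).
#' @param max_qtls search cap for [infer_qtl_model()] (default 6).
#' @param max_gap_mb imputation gap rule in Mb (default 26).
#' @return list: `panel` (prepared), `prep_report`, `summary`, `graph`,
#'   `comparisons`, `model` (a `qtl_model`).
#' @export
sequential_analysis <- function(panel, min_n = 12, alpha = 0.05,
                                max_qtls = 6, max_gap_mb = 26) {
  imp <- impute_genotypes(panel, max_gap_mb = max_gap_mb)
  prep <- prepare_phenotypes(imp$panel)
  panel <- prep$panel
  summary <- strain_donor_summary(panel)
  sel <- select_strains(panel, "narrow", min_n = min_n, summary = summary)
  strains <- attr(sel, "strains")
  if (length(strains) < 1) stop("no strain meets the group-size criterion")
  graph <- build_mst(summary$strain_regions[strains])
  comparisons <- run_comparisons(graph, panel, summary = summary,
                                 alpha = alpha)
  model <- infer_qtl_model(comparisons, max_qtls = max_qtls)
  list(panel = panel, prep_report = prep$report, summary = summary,
       graph = graph, comparisons = comparisons, model = model)
}

#' End-to-end common segment analysis
#'
#' Imputes, prepares phenotypes, selects strains under the narrow or broad
#' criterion, classifies each strain as QTL-positive/negative by LSD, and
#' tests the single-QTL shared-segment predicate.
#'
#' @inheritParams sequential_analysis
#' @param mode `"narrow"` or `"broad"`.
#' @return list: `classifications`, `shared` (see [shared_region_test()]),
#'   `selection`.
#' @export
common_segment_analysis <- function(panel, mode = c("narrow", "broad"),
                                    min_n = 12, alpha = 0.05,
                                    max_gap_mb = 26) {
  mode <- match.arg(mode)
  imp <- impute_genotypes(panel, max_gap_mb = max_gap_mb)
  prep <- prepare_phenotypes(imp$panel)
  panel <- prep$panel
  summary <- strain_donor_summary(panel)
  sel <- select_strains(panel, mode, min_n = min_n, summary = summary)
  cls <- classify_strains(panel, sel, alpha = alpha)
  shared <- suppressWarnings(shared_region_test(cls, panel, summary = summary))
  list(classifications = cls, shared = shared, selection = sel)
}
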