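#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential-expression filter with cross-experiment reproducibility
#'
#' Applies the fold-change / FDR filter to each expression experiment and
#' intersects the per-experiment pass sets, restricted to genes inside the
#' congenic donor-region interval. By default a gene passes an experiment if
#' `|log2fc| > fc_threshold_log2` OR its BH q-value is below `q_threshold`
#' (the "1.5-fold change and/or FDR < 0.05" rule; 2^0.58 is a 1.5-fold
#' change); `combine = "and"` requires both sub-filters.
#'
#' @param experiments list of data.frames, each with columns `gene_id`,
#'   `chrom`, `start`, `end`, `log2fc`, `p_value` (q-values are computed
#'   here via [bh_fdr()] over each experiment's gene universe).
#' @param region an [interval_set()]: the donor-region interval candidates
#'   must overlap (NULL = no restriction).
#' @param fc_threshold_log2 absolute log2 fold-change cutoff (default 0.58).
#' @param q_threshold FDR cutoff (default 0.05).
#' @param combine `"or"` (default) or `"and"`.
#' @return list: `per_experiment` (list of data.frames with `q` and `pass`
#'   added), `pass_sets` (character vectors of gene ids), `reproducible`
#'   (genes passing every experiment, inside `region`).
#' @export
de_filter <- function(experiments, region = NULL, fc_threshold_log2 = 0.58,
                      q_threshold = 0.05, combine = c("or", "and")) {
  combine <- match.arg(combine)
  stopifnot(length(experiments) >= 1)
  universes <- lapply(experiments, function(e) e$gene_id)
  common <- Reduce(intersect, universes)
  if (!all(vapply(universes, function(u) setequal(u, common), logical(1)))) {
    warning("experiments have different gene universes; restricting to the intersection")
  }
  per <- lapply(experiments, function(e) {
    e <- e[e$gene_id %in% common, , drop = FALSE]
    e$q <- bh_fdr(e$p_value)
    fc_ok <- abs(e$log2fc) > fc_threshold_log2
    q_ok <- e$q < q_threshold
    e$pass <- if (combine == "or") fc_ok | q_ok else fc_ok & q_ok
    e
  })
  pass_sets <- lapply(per, function(e) e$gene_id[e$pass])
  repro <- Reduce(intersect, pass_sets)
  if (!is.null(region)) {
    coords <- per[[1]][match(repro, per[[1]]$gene_id), , drop = FALSE]
    inside <- vapply(seq_len(nrow(coords)), function(i) {
      !ivs_is_empty(ivs_intersect(region, interval_set(coords$start[i],
                                                       coords$end[i])))
    }, logical(1))
    repro <- repro[inside]
  }
  list(per_experiment = per, pass_sets = pass_sets, reproducible = repro)
}

#' Cross-tabulate candidate-gene evidence within QTL intervals
#'
#' Restricts a gene table to genes overlapping any QTL interval and counts
#' genes in every cell of the three-way evidence cross (differential
#' expression, missense variant, human GWAS orthologue). Variant-effect and
#' orthologue evidence are consumed as precomputed boolean flags.
#'
#' @param qtls data.frame with columns `start`, `end` (QTL intervals), or an
#'   empty data.frame for no QTLs.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @param flags data.frame with columns `gene_id`,
#'   `differential_expression`, `missense_variant`, `human_gwas_orthologue`
#'   (logical).
#' @return list: `table` (per-gene flags for genes inside QTLs) and
#'   `counts` (data.frame of all 2^3 intersection cells with `n`).
#' @export
overlap_evidence <- function(qtls, genes, flags) {
  flag_names <- c("differential_expression", "missense_variant",
                  "human_gwas_orthologue")
  stopifnot(all(c("gene_id", flag_names) %in% names(flags)))
  if (nrow(qtls) == 0 || nrow(genes) == 0) {
    tab <- genes[0, "gene_id", drop = FALSE]
  } else {
    qset <- interval_set(qtls$start, qtls$end)
    inside <- vapply(seq_len(nrow(genes)), function(i) {
      !ivs_is_empty(ivs_intersect(qset, interval_set(genes$start[i],
                                                     genes$end[i])))
    }, logical(1))
    tab <- genes[inside, "gene_id", drop = FALSE]
  }
  m <- flags[match(tab$gene_id, flags$gene_id), flag_names, drop = FALSE]
  m[is.na(m)] <- FALSE
  tab <- cbind(tab, m)
  rownames(tab) <- NULL
  cells <- expand.grid(differential_expression = c(FALSE, TRUE),
                       missense_variant = c(FALSE, TRUE),
                       human_gwas_orthologue = c(FALSE, TRUE))
  cells$n <- vapply(seq_len(nrow(cells)), function(i) {
    sum(tab$differential_expression == cells$differential_expression[i] &
          tab$missense_variant == cells$missense_variant[i] &
          tab$human_gwas_orthologue == cells$human_gwas_orthologue[i])
  }, integer(1))
  list(table = tab, counts = cells)
}
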