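#' Select strains and mice for the common segment analysis
#'
#' Two selection modes mirror the narrow and broad analyses. `narrow`
#' restricts donor mice to full-length donor regions and keeps strains with
#' at least `min_n` mice per genotype group (default 12). `broad` keeps
#' nearly all mice (full and partial donors), excluding only strains with
#' any genotype group smaller than `broad_floor` (default 2, the smallest
#' group a contrast can use).
#'
#' @param panel a prepared [congenic_panel()].
#' @param mode `"narrow"` or `"broad"`.
#' @param min_n per-genotype minimum for the narrow mode (default 12).
#' @param broad_floor per-genotype floor for the broad mode (default 2).
#' @param summary optional precomputed [strain_donor_summary()].
#' @return data.frame of selected mice: `mouse_id`, `strain`, `genotype`
#'   (`host`/`donor`), with the selected strain ids in
#'   `attr(, "strains")`.
#' @export
select_strains <- function(panel, mode = c("narrow", "broad"), min_n = 12,
                           broad_floor = 2, summary = NULL) {
  mode <- match.arg(mode)
  if (nrow(panel$pheno) == 0) {
    out <- data.frame(mouse_id = character(), strain = character(),
                      genotype = character(), stringsAsFactors = FALSE)
    attr(out, "strains") <- character()
    return(out)
  }
  if (is.null(summary)) summary <- strain_donor_summary(panel)
  st <- summary$mouse_status
  st <- st[st$mouse_id %in% panel$pheno$mouse_id, , drop = FALSE]
  donor_ok <- if (mode == "narrow") st$is_full else st$is_donor
  floor_n <- if (mode == "narrow") min_n else broad_floor
  keep_strains <- character()
  for (s in unique(st$strain)) {
    rows <- st[st$strain == s, , drop = FALSE]
    n_host <- sum(!rows$is_donor)
    n_don <- sum(donor_ok[st$strain == s])
    if (n_host >= floor_n && n_don >= floor_n) keep_strains <- c(keep_strains, s)
  }
  sel <- st[st$strain %in% keep_strains & (!st$is_donor | donor_ok), , drop = FALSE]
  out <- data.frame(mouse_id = sel$mouse_id, strain = sel$strain,
                    genotype = ifelse(sel$is_donor, "donor", "host"),
                    stringsAsFactors = FALSE)
  attr(out, "strains") <- sort(keep_strains)
  out
}

#' Classify strains as QTL-positive or QTL-negative
#'
#' Fits one joint model over the selected mice (body weight covariate, then
#' strain-by-genotype cell means) and performs a Fisher's LSD contrast of
#' donor versus host adjusted means within each strain, using the joint
#' residual mean square. A strain is `positive` when the two genotype groups
#' differ at p < 0.05 (unadjusted, as is conventional for LSD), `negative`
#' otherwise, and `untestable` when a genotype group has fewer than 2 mice.
#'
#' @param panel a prepared [congenic_panel()] (phenotype column `y`).
#' @param selection a [select_strains()] result.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per strain: `strain`, `n_host`,
#'   `n_donor`, `mean_host`, `mean_donor`, `p`, `verdict`.
#' @export
classify_strains <- function(panel, selection, alpha = 0.05) {
  strains <- attr(selection, "strains")
  if (length(strains) < 2) stop("need at least 2 strains to classify")
  ph <- panel$pheno[match(selection$mouse_id, panel$pheno$mouse_id), ,
                    drop = FALSE]
  d <- data.frame(y = ph$y, bw = ph$bw_g,
                  cell = factor(paste(selection$strain, selection$genotype,
                                      sep = "||")),
                  stringsAsFactors = FALSE)
  fit <- fit_glm(d, "y", c("bw", "cell"))
  am <- adjusted_means(fit, "cell")
  nn <- table(d$cell)
  out <- NULL
  for (s in strains) {
    ch <- paste(s, "host", sep = "||"); cd <- paste(s, "donor", sep = "||")
    n_h <- if (ch %in% names(nn)) nn[[ch]] else 0L
    n_d <- if (cd %in% names(nn)) nn[[cd]] else 0L
    if (n_h < 2 || n_d < 2) {
      out <- rbind(out, data.frame(strain = s, n_host = n_h, n_donor = n_d,
                                   mean_host = NA_real_, mean_donor = NA_real_,
                                   p = NA_real_, verdict = "untestable",
                                   stringsAsFactors = FALSE))
      next
    }
    ct <- lsd_contrast(am[[cd]], am[[ch]], n_d, n_h, fit$mse, fit$df_residual)
    out <- rbind(out, data.frame(strain = s, n_host = n_h, n_donor = n_d,
                                 mean_host = am[[ch]], mean_donor = am[[cd]],
                                 p = ct$p,
                                 verdict = if (ct$p < alpha) "positive" else "negative",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Test the single-QTL shared-segment hypothesis
#'
#' Under a single-QTL model, some chromosomal region must be donor-derived
#' (`H`) in every phenotype-positive strain and host (`A`) in every
#' phenotype-negative strain. This evaluates that predicate at every marker,
#' using each strain's full-length donor region.
#'
#' @param classifications a [classify_strains()] result.
#' @param panel the [congenic_panel()].
#' @param summary optional precomputed [strain_donor_summary()].
#' @return list: `per_marker` data.frame (`marker_id`, `pos_bp`, `shared`),
#'   `any_shared` (the overall verdict), `vacuous` (TRUE when there was no
#'   positive or no negative strain, making the predicate uninformative).
#' @export
shared_region_test <- function(classifications, panel, summary = NULL) {
  if (is.null(summary)) summary <- strain_donor_summary(panel)
  pos <- classifications$strain[classifications$verdict == "positive"]
  neg <- classifications$strain[classifications$verdict == "negative"]
  vacuous <- length(pos) == 0 || length(neg) == 0
  if (vacuous) {
    warning("shared-region predicate is vacuous: need >= 1 positive and >= 1 negative strain")
  }
  covers <- function(strain_ids, p) {
    vapply(strain_ids, function(s) {
      reg <- summary$strain_regions[[s]]
      !is.null(reg) && ivs_covers(reg, p)
    }, logical(1))
  }
  shared <- vapply(panel$map$pos_bp, function(p) {
    !vacuous && all(covers(pos, p)) && !any(covers(neg, p))
  }, logical(1))
  list(per_marker = data.frame(marker_id = panel$map$marker_id,
                               pos_bp = panel$map$pos_bp, shared = shared,
                               stringsAsFactors = FALSE),
       any_shared = any(shared), vacuous = vacuous)
}
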