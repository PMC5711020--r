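#' Genome-scan significance thresholds
#'
#' Bonferroni-style marker-count correction on the -log10 scale:
#' `-log10(alpha / n_markers)`. With 148 markers this gives 3.47 at
#' alpha = 0.05 (significant) and 2.37 at alpha = 0.63 (suggestive, the
#' per-genome rate of one false positive under the standard genome-scan
#' convention).
#'
#' @param n_markers number of markers scanned.
#' @param alpha type-I level before correction.
#' @return `-log10(alpha / n_markers)`.
#' @export
scan_threshold <- function(n_markers, alpha) {
  stopifnot(n_markers >= 1, alpha > 0, alpha <= 1)
  -log10(alpha / n_markers)
}

#' Pooled per-marker association scan
#'
#' Treats all congenic mice as one mapping population and fits, for each
#' marker, an OLS model of the prepared phenotype with sequential (Type-1)
#' sums of squares, the marker genotype entering last so its test is
#' adjusted for the preceding terms (body weight, then strain by default).
#' The strain factor keeps one level per strain segregating at the marker;
#' non-segregating strains are pooled into a single background level and
#' still contribute to covariate estimation. Markers monomorphic in the
#' analyzed mice get a missing score. Mice with a missing genotype at a
#' marker are dropped for that marker only.
#'
#' @param panel a prepared [congenic_panel()] (phenotype column `y` present;
#'   see [prepare_phenotypes()]).
#' @param alpha significant-threshold level (default 0.05).
#' @param alpha_suggestive suggestive-threshold level (default 0.63).
#' @param term_order covariate/factor entry order before genotype; any of
#'   `"bw"`, `"strain"` (default both, in that order).
#' @return An object of class `scan_result`: per-marker data.frame `markers`
#'   (marker_id, pos_bp, neg_log10_p, mean_A, mean_H, n_A, n_H, cohens_d),
#'   thresholds, and the peak marker row.
#' @export
scan_markers <- function(panel, alpha = 0.05, alpha_suggestive = 0.63,
                         term_order = c("bw", "strain")) {
  if (is.null(panel$pheno$y)) {
    stop("panel has no prepared phenotype; run prepare_phenotypes() first")
  }
  stopifnot(all(term_order %in% c("bw", "strain")))
  ph <- panel$pheno
  n_mark <- nrow(panel$map)
  res <- data.frame(marker_id = panel$map$marker_id,
                    pos_bp = panel$map$pos_bp,
                    neg_log10_p = NA_real_, mean_A = NA_real_,
                    mean_H = NA_real_, n_A = NA_integer_, n_H = NA_integer_,
                    cohens_d = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(n_mark)) {
    g <- panel$geno[ph$mouse_id, j]
    use <- g != "X"
    gj <- g[use]
    if (length(unique(gj)) < 2) next
    d <- data.frame(y = ph$y[use], bw = ph$bw_g[use],
                    strain = ph$strain[use], genotype = factor(gj, c("A", "H")),
                    stringsAsFactors = FALSE)
    seg <- unique(d$strain[d$genotype == "H"])
    d$strain <- factor(ifelse(d$strain %in% seg, d$strain, ".background"))
    fit <- suppressWarnings(
      fit_glm(d, "y", c(term_order, "genotype"))
    )
    res$neg_log10_p[j] <- -log10(term_p(fit, "genotype"))
    am <- adjusted_means(fit, "genotype")
    res$mean_A[j] <- am[["A"]]; res$mean_H[j] <- am[["H"]]
    res$n_A[j] <- sum(d$genotype == "A"); res$n_H[j] <- sum(d$genotype == "H")
    res$cohens_d[j] <- cohens_d(d$y[d$genotype == "A"], d$y[d$genotype == "H"])
  }
  sig <- scan_threshold(n_mark, alpha)
  sug <- scan_threshold(n_mark, alpha_suggestive)
  peak <- if (all(is.na(res$neg_log10_p))) NA_integer_ else
    which.max(res$neg_log10_p)
  structure(list(markers = res, significant_threshold = sig,
                 suggestive_threshold = sug, peak = peak,
                 alpha = alpha, alpha_suggestive = alpha_suggestive),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result: %d markers; thresholds %.2f (significant) / %.2f (suggestive)>\n",
              nrow(x$markers), x$significant_threshold, x$suggestive_threshold))
  if (!is.na(x$peak)) {
    p <- x$markers[x$peak, ]
    cat(sprintf("  peak: %s at %s bp, -log10 p = %.2f, D = %.2f\n",
                p$marker_id, format(p$pos_bp, big.mark = ","), p$neg_log10_p,
                p$cohens_d))
  }
  invisible(x)
}

#' Drop-based QTL support intervals
#'
#' For each local peak of the -log10 p profile that exceeds the significant
#' threshold, extends left and right over consecutive markers whose score
#' stays within `drop` units of that peak, stopping where the profile first
#' falls below `peak - drop`. Overlapping intervals from neighboring peaks
#' are merged (the stronger peak is reported).
#'
#' @param scan a [scan_markers()] result.
#' @param drop support-interval drop in -log10 p units (default 2).
#' @return data.frame with one row per interval: `start_bp`, `end_bp`,
#'   `peak_marker`, `peak_pos_bp`, `peak_neg_log10_p`.
#' @export
qtl_support_interval <- function(scan, drop = 2.0) {
  v <- scan$markers$neg_log10_p
  pos <- scan$markers$pos_bp
  v[is.na(v)] <- -Inf
  n <- length(v)
  thr <- scan$significant_threshold
  peaks <- which(v >= thr &
                   v >= c(-Inf, v[-n]) &
                   v >= c(v[-1], -Inf))
  out <- NULL
  for (p in peaks) {
    lo <- p
    while (lo > 1 && v[lo - 1] >= v[p] - drop) lo <- lo - 1
    hi <- p
    while (hi < n && v[hi + 1] >= v[p] - drop) hi <- hi + 1
    out <- rbind(out, data.frame(start_bp = pos[lo], end_bp = pos[hi],
                                 peak_marker = scan$markers$marker_id[p],
                                 peak_pos_bp = pos[p],
                                 peak_neg_log10_p = v[p],
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      peak_marker = character(), peak_pos_bp = numeric(),
                      peak_neg_log10_p = numeric(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$start_bp, -out$peak_neg_log10_p), , drop = FALSE]
  merged <- out[1, , drop = FALSE]
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      last <- nrow(merged)
      if (out$start_bp[i] <= merged$end_bp[last]) {
        merged$end_bp[last] <- max(merged$end_bp[last], out$end_bp[i])
        if (out$peak_neg_log10_p[i] > merged$peak_neg_log10_p[last]) {
          merged$peak_marker[last] <- out$peak_marker[i]
          merged$peak_pos_bp[last] <- out$peak_pos_bp[i]
          merged$peak_neg_log10_p[last] <- out$peak_neg_log10_p[i]
        }
      } else {
        merged <- rbind(merged, out[i, , drop = FALSE])
      }
    }
  }
  rownames(merged) <- NULL
  merged
}
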