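#' Remove flagged mice from a panel
#'
#' Drops mice whose exclusion flag is set (sick at necropsy, tumors or other
#' gross morphology), mirroring the first phenotype-preparation step.
#'
#' @param panel a [congenic_panel()].
#' @return The filtered panel; a message reports the count removed.
#' @export
apply_exclusions <- function(panel) {
  drop <- panel$pheno$excluded
  if (any(drop)) {
    message(sprintf("apply_exclusions: removing %d of %d mice", sum(drop),
                    length(drop)))
  }
  if (all(drop)) warning("all mice excluded; panel is empty")
  panel$pheno <- panel$pheno[!drop, , drop = FALSE]
  panel$geno <- panel$geno[panel$pheno$mouse_id, , drop = FALSE]
  panel
}

.moment_skewness <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

.moment_kurtosis <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^4) / s^4
}

.ks_normal <- function(x) {
  # parameters estimated from the data (Lilliefors-style caveat: the
  # reported p-value is anti-conservative for strict normality testing)
  suppressWarnings(stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
}

#' Diagnose the trait distribution and log-transform if needed
#'
#' Computes moment-based skewness and kurtosis of the raw weights and applies
#' a natural-log transform when the raw skewness exceeds `skew_threshold` or
#' a Kolmogorov-Smirnov test against a normal with estimated mean/sd rejects
#' at `alpha`. A KS test of the (possibly transformed) data confirms the
#' result. Adipose depot weights are typically right-skewed, so real panels
#' land on the transformed branch.
#'
#' @param weights positive numeric vector (depot weights in grams); names are
#'   used to identify offending mice in error messages.
#' @param skew_threshold raw skewness above which the transform is applied
#'   (default 0.5).
#' @param alpha significance level of the raw-data KS screen (default 0.05).
#' @return list with `values` (transformed or raw vector) and `report`: raw
#'   and final skewness/kurtosis, KS statistic and p for raw and final data,
#'   and `transform_applied`.
#' @export
diagnose_and_transform <- function(weights, skew_threshold = 0.5, alpha = 0.05) {
  if (anyNA(weights)) stop("missing weights; drop missing phenotypes first")
  if (any(weights <= 0)) {
    who <- if (is.null(names(weights))) which(weights <= 0)[1] else
      names(weights)[weights <= 0][1]
    stop("non-positive weight for mouse ", who)
  }
  if (stats::sd(weights) == 0) stop("zero variance in weights")
  raw_skew <- .moment_skewness(weights)
  raw_kurt <- .moment_kurtosis(weights)
  ks_raw <- .ks_normal(weights)
  transform <- raw_skew > skew_threshold || ks_raw$p.value < alpha
  values <- if (transform) log(weights) else weights
  ks_final <- .ks_normal(values)
  list(values = values,
       report = list(transform_applied = transform,
                     raw_skewness = raw_skew, raw_kurtosis = raw_kurt,
                     final_skewness = .moment_skewness(values),
                     final_kurtosis = .moment_kurtosis(values),
                     ks_raw_stat = unname(ks_raw$statistic),
                     ks_raw_p = ks_raw$p.value,
                     ks_final_stat = unname(ks_final$statistic),
                     ks_final_p = ks_final$p.value))
}

#' Screen candidate covariates by Pearson correlation
#'
#' Correlates depot weight with body weight and age (and body weight with
#' age, for context). A covariate is retained when `|r| > corr_threshold`
#' and p < 0.05. In this design body weight is strongly correlated with
#' depot weight while age, tightly controlled by the necropsy schedule, is
#' not; the defaults reproduce that choice (body weight in, age out).
#'
#' @param panel a [congenic_panel()] (mice with missing depot weight are
#'   ignored here).
#' @param corr_threshold minimum absolute correlation to retain (default 0.3).
#' @return list with `correlations` (data.frame: pair, r, p) and `retained`
#'   (character vector of covariate names).
#' @export
screen_covariates <- function(panel, corr_threshold = 0.3) {
  ph <- panel$pheno[!is.na(panel$pheno$depot_g), , drop = FALSE]
  if (nrow(ph) < 3) stop("need at least 3 mice with phenotypes")
  pairs <- list(c("depot_g", "bw_g"), c("depot_g", "age_d"), c("bw_g", "age_d"))
  res <- do.call(rbind, lapply(pairs, function(p) {
    x <- ph[[p[1]]]; y <- ph[[p[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(var1 = p[1], var2 = p[2], r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y)
    data.frame(var1 = p[1], var2 = p[2], r = unname(ct$estimate),
               p = ct$p.value)
  }))
  dep <- res[res$var1 == "depot_g", , drop = FALSE]
  keep <- dep$var2[!is.na(dep$r) & abs(dep$r) > corr_threshold & dep$p < 0.05]
  retained <- intersect(c("bw_g", "age_d"), keep)
  list(correlations = res, retained = retained)
}

#' Full phenotype preparation
#'
#' Convenience wrapper running the three preparation steps: exclusions,
#' distribution diagnosis with optional log transform, covariate screening.
#' Mice with missing depot weight are dropped (with a message). The analysis
#' phenotype is stored in a `y` column of the panel's phenotype table; all
#' mapping stages read it.
#'
#' @inheritParams diagnose_and_transform
#' @inheritParams screen_covariates
#' @return list with `panel` (prepared) and `report` (exclusion counts,
#'   distribution report, covariate screen).
#' @export
prepare_phenotypes <- function(panel, skew_threshold = 0.5,
                               corr_threshold = 0.3) {
  n0 <- nrow(panel$pheno)
  panel <- apply_exclusions(panel)
  n_excl <- n0 - nrow(panel$pheno)
  miss <- is.na(panel$pheno$depot_g)
  if (any(miss)) {
    message(sprintf("prepare_phenotypes: dropping %d mice with missing depot weight",
                    sum(miss)))
    panel$pheno <- panel$pheno[!miss, , drop = FALSE]
    panel$geno <- panel$geno[panel$pheno$mouse_id, , drop = FALSE]
  }
  w <- panel$pheno$depot_g
  names(w) <- panel$pheno$mouse_id
  dt <- diagnose_and_transform(w, skew_threshold = skew_threshold)
  panel$pheno$y <- unname(dt$values)
  cov <- screen_covariates(panel, corr_threshold = corr_threshold)
  list(panel = panel,
       report = list(n_excluded = n_excl, n_missing_phenotype = sum(miss),
                     distribution = dt$report, covariates = cov))
}
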