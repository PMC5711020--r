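#' Configuration for the synthetic congenic panel generator
#'
#' Defaults emulate the study conditions the pipeline targets: a
#' single-chromosome panel of 148 markers spanning 3-124.6 Mb; 12 congenic
#' strains in three branching lineages (prefixes 1, 3 and 4) whose nested
#' donor fragments place recombination breakpoints around four linked QTLs;
#' planted QTLs at 43.5, 52.5, 54.26 and 113.915 Mb with standardized
#' effects +1, +1, -1, +1 (pooled-SD units of log depot weight; QTL2 and
#' QTL3 have equal magnitude and opposite sign, so a donor region spanning
#' both is phenotypically silent); body weight Normal(31, 3) g; log-normal
#' depot weights around 0.5 g with residual SD 0.4 on the log scale and a
#' body-weight slope of 0.08 per gram (giving r(depot, bw) about 0.5).
#'
#' @param n_per_genotype mice per genotype group per strain (default 30).
#' @param marker_pos_bp marker positions (bp, single chromosome).
#' @param strains named list of donor [interval_set()]s.
#' @param qtls data.frame with `pos_bp` and `effect` (signed, pooled-SD
#'   units).
#' @param bw_mean,bw_sd body-weight distribution (g).
#' @param log_depot_baseline intercept of log depot weight (log grams).
#' @param bw_slope slope of log depot weight on centered body weight.
#' @param resid_sd residual SD of log depot weight.
#' @param lognormal_resid if TRUE (default) residuals act on the log scale,
#'   making raw depot weights right-skewed.
#' @param partial_prob probability a donor mouse carries a truncated
#'   (partial) fragment (default 0.15).
#' @param truncate_both_ends if TRUE a truncation keeps the proximal or
#'   distal part at random; default FALSE keeps the proximal part.
#' @param missing_rate genotype missingness rate (default 0.02).
#' @param exclusion_rate rate of mice flagged for exclusion (default 0.01).
#' @param age_mean,age_sd necropsy age (days).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_genotype = 30,
                       marker_pos_bp = default_marker_positions(),
                       strains = default_strains(),
                       qtls = default_qtls(),
                       bw_mean = 31, bw_sd = 3,
                       log_depot_baseline = log(0.5),
                       bw_slope = 0.08,
                       resid_sd = 0.4,
                       lognormal_resid = TRUE,
                       partial_prob = 0.15,
                       truncate_both_ends = FALSE,
                       missing_rate = 0.02,
                       exclusion_rate = 0.01,
                       age_mean = 180, age_sd = 2,
                       seed = 1) {
  span <- range(marker_pos_bp)
  if (any(qtls$pos_bp < span[1] | qtls$pos_bp > span[2])) {
    stop("QTL position outside the marker span")
  }
  structure(list(n_per_genotype = n_per_genotype,
                 marker_pos_bp = marker_pos_bp, strains = strains,
                 qtls = qtls, bw_mean = bw_mean, bw_sd = bw_sd,
                 log_depot_baseline = log_depot_baseline,
                 bw_slope = bw_slope, resid_sd = resid_sd,
                 lognormal_resid = lognormal_resid,
                 partial_prob = partial_prob,
                 truncate_both_ends = truncate_both_ends,
                 missing_rate = missing_rate,
                 exclusion_rate = exclusion_rate,
                 age_mean = age_mean, age_sd = age_sd, seed = seed),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_marker_positions <- function() {
  specials <- c(3, 42, 43.5, 44, 45, 48, 50, 52.5, 53.5, 53.884418, 54,
                54.242579, 54.26, 54.28677, 55, 56, 58.262383, 58.3, 60,
                100, 108.91501, 113.91501, 118.91501, 119, 124.59511) * 1e6
  fillers <- round(seq(3.4e6, 124.2e6, length.out = 148 - length(specials)))
  pos <- sort(unique(round(c(specials, fillers))))
  stopifnot(length(pos) == 148)
  pos
}

#' @rdname sim_config
#' @export
default_strains <- function() {
  mb <- function(s, e) interval_set(s * 1e6, e * 1e6)
  list("1"       = mb(3, 124.59511),
       "1.1"     = mb(3, 56),
       "1.2"     = mb(3, 45),
       "3"       = mb(42, 119),
       "3.1"     = mb(42, 58.3),
       "3.1.1"   = mb(42, 55),
       "3.1.1.1" = mb(42, 53.5),
       "3.1.1.2" = mb(42, 45),
       "3.1.2"   = mb(42, 50),
       "4"       = mb(48, 58.3),
       "4.1"     = mb(48, 53.5),
       "4.2"     = mb(54, 58.3))
}

#' @rdname sim_config
#' @export
default_qtls <- function() {
  data.frame(qtl = c("QTL1", "QTL2", "QTL3", "QTL4"),
             pos_bp = c(43.5e6, 52.5e6, 54.26e6, 113.91501e6),
             effect = c(1, 1, -1, 1), stringsAsFactors = FALSE)
}

#' Simulate a congenic panel
#'
#' Draws, for each strain, `n_per_genotype` donor mice and the same number
#' of homozygous host littermates. A donor mouse receives the strain's
#' donor region, truncated with probability `partial_prob` at a single
#' recombination point uniform on the region. Genotypes are `H` at markers
#' inside the mouse's (possibly truncated) region, `A` elsewhere, with `X`
#' masking at the missingness rate. Body weight is Normal; log depot weight
#' is baseline + slope * (bw - mean) + sum of planted QTL effects carried by
#' the mouse's region + Normal noise. Effects are scaled so that a planted
#' effect equals the expected Cohen's D of log depot weight at a fully
#' linked marker (the scale includes the body-weight contribution to the
#' within-genotype SD). Fully reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return list: `panel` (a [congenic_panel()]) and `truth` (planted QTLs
#'   on the bp scale, per-mouse donor regions, and the effect scale used).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pos <- config$marker_pos_bp
  n_mark <- length(pos)
  effect_scale <- sqrt(config$resid_sd^2 +
                         (config$bw_slope * config$bw_sd)^2)
  rows <- list(); gmat <- list(); truth_regions <- list()
  mouse_no <- 0L
  for (s in names(config$strains)) {
    full <- config$strains[[s]]
    for (gtype in c("host", "donor")) {
      for (k in seq_len(config$n_per_genotype)) {
        mouse_no <- mouse_no + 1L
        mid <- sprintf("M%04d", mouse_no)
        if (gtype == "host") {
          region <- interval_set()
        } else {
          region <- full
          if (stats::runif(1) < config$partial_prob) {
            x <- round(stats::runif(1, min(full$start), max(full$end)))
            keep_proximal <- !config$truncate_both_ends ||
              stats::runif(1) < 0.5
            region <- if (keep_proximal) {
              ivs_intersect(full, interval_set(1, x))
            } else {
              ivs_intersect(full, interval_set(x, max(full$end)))
            }
            if (ivs_is_empty(region)) region <- full
          }
        }
        g <- ifelse(ivs_covers(region, pos), "H", "A")
        if (config$missing_rate > 0) {
          g[stats::runif(n_mark) < config$missing_rate] <- "X"
        }
        bw <- stats::rnorm(1, config$bw_mean, config$bw_sd)
        qtl_term <- sum(config$qtls$effect *
                          ivs_covers(region, config$qtls$pos_bp))
        log_d <- config$log_depot_baseline +
          config$bw_slope * (bw - config$bw_mean) +
          effect_scale * qtl_term
        noise <- stats::rnorm(1, 0, config$resid_sd)
        depot <- if (config$lognormal_resid) exp(log_d + noise) else
          exp(log_d) + noise * exp(config$log_depot_baseline)
        excluded <- stats::runif(1) < config$exclusion_rate
        rows[[mouse_no]] <- data.frame(
          mouse_id = mid, strain = s, depot_g = depot, bw_g = bw,
          age_d = round(stats::rnorm(1, config$age_mean, config$age_sd)),
          excluded = excluded, reason = if (excluded) "tumor" else "",
          stringsAsFactors = FALSE)
        gmat[[mouse_no]] <- g
        truth_regions[[mid]] <- region
      }
    }
  }
  pheno <- do.call(rbind, rows)
  geno <- do.call(rbind, gmat)
  rownames(geno) <- pheno$mouse_id
  map <- data.frame(marker_id = sprintf("mk%03d", seq_len(n_mark)),
                    chrom = "9", pos_bp = pos, stringsAsFactors = FALSE)
  panel <- congenic_panel(map, geno, pheno)
  list(panel = panel,
       truth = list(qtls = config$qtls, effect_scale = effect_scale,
                    regions = truth_regions))
}

#' Write a panel (plus simulation truth) to disk
#'
#' Emits the three input files [read_panel()] consumes -- `map.tsv`,
#' `genotypes.tsv`, `phenotypes.csv` -- plus `truth.json` when simulation
#' truth is supplied.
#'
#' @param panel a [congenic_panel()].
#' @param out_dir output directory (created if missing).
#' @param truth optional truth list from [simulate_panel()].
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, out_dir, truth = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("map.tsv", "genotypes.tsv",
                                "phenotypes.csv", "truth.json"))
  utils::write.table(panel$map, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- data.frame(mouse_id = rownames(panel$geno), panel$geno,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(g, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ph <- panel$pheno
  for (col in c("depot_g", "bw_g")) {
    ph[[col]] <- format(ph[[col]], digits = 15, trim = TRUE)
  }
  utils::write.table(ph, paths[3], sep = ",", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth)) {
    tr <- list(qtls = truth$qtls, effect_scale = truth$effect_scale,
               regions = lapply(truth$regions, function(r) {
                 list(start = r$start, end = r$end)
               }))
    jsonlite::write_json(tr, paths[4], auto_unbox = TRUE, digits = NA)
  } else {
    paths <- paths[1:3]
  }
  invisible(paths)
}
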