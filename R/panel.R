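#' Assemble a congenic panel object
#'
#' A `congenic_panel` bundles everything the mapping stages consume: the
#' marker map, the per-mouse genotype matrix (codes `A` = homozygous host,
#' `H` = heterozygous donor, `X` = missing; the backcross design has no
#' homozygous-donor state), and the phenotype table. Strain metadata maps
#' strain ids to descriptive labels.
#'
#' @param map data.frame with columns `marker_id`, `chrom`, `pos_bp`;
#'   positions strictly increasing within a chromosome, marker ids unique.
#' @param geno character matrix, rows = mice (rownames = mouse ids),
#'   columns = markers in map order; cells in `{A, H, X}`.
#' @param pheno data.frame with columns `mouse_id`, `strain`, `depot_g`,
#'   `bw_g`, `age_d`, `excluded` (logical), `reason`.
#' @param strains optional data.frame with columns `strain_id`, `label`;
#'   defaults to the strains present in `pheno`.
#' @return An object of class `congenic_panel`.
#' @export
congenic_panel <- function(map, geno, pheno, strains = NULL) {
  map <- as.data.frame(map)
  pheno <- as.data.frame(pheno)
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(map))) {
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  }
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.numeric(map$pos_bp)
  if (anyDuplicated(map$marker_id)) {
    stop("duplicate marker_id in map: ",
         paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  }
  if (any(map$pos_bp < 1)) stop("marker positions must be >= 1 (1-based bp)")
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("marker positions must be strictly increasing within chromosome ", ch)
    }
  }

  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map)) {
    stop("genotype matrix has ", ncol(geno), " columns but map has ",
         nrow(map), " markers")
  }
  if (is.null(rownames(geno))) stop("genotype matrix must have mouse ids as rownames")
  colnames(geno) <- map$marker_id
  bad <- which(array(!(geno %in% c("A", "H", "X")), dim(geno)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("unknown genotype code '%s' for mouse '%s' at marker '%s'",
                 geno[bad[1, 1], bad[1, 2]],
                 rownames(geno)[bad[1, 1]], colnames(geno)[bad[1, 2]]))
  }

  needp <- c("mouse_id", "strain", "depot_g", "bw_g", "age_d", "excluded", "reason")
  if (!all(needp %in% names(pheno))) {
    stop("phenotype table must have columns: ", paste(needp, collapse = ", "))
  }
  pheno$mouse_id <- as.character(pheno$mouse_id)
  pheno$strain <- as.character(pheno$strain)
  pheno$excluded <- as.logical(pheno$excluded)
  pheno$reason <- as.character(pheno$reason)
  if (anyDuplicated(pheno$mouse_id)) {
    stop("duplicate mouse_id in phenotype table: ",
         paste(unique(pheno$mouse_id[duplicated(pheno$mouse_id)]), collapse = ", "))
  }
  if (!setequal(pheno$mouse_id, rownames(geno))) {
    stop("mouse ids differ between genotype matrix and phenotype table")
  }
  geno <- geno[pheno$mouse_id, , drop = FALSE]
  if (any(pheno$excluded & !nzchar(pheno$reason))) {
    stop("excluded mice must carry a reason")
  }
  ok <- !is.na(pheno$depot_g)
  if (any(ok & pheno$depot_g <= 0)) {
    stop("non-positive depot weight for mouse ",
         pheno$mouse_id[which(ok & pheno$depot_g <= 0)[1]])
  }
  if (any(ok & pheno$depot_g > pheno$bw_g)) {
    stop("depot weight exceeds body weight for mouse ",
         pheno$mouse_id[which(ok & pheno$depot_g > pheno$bw_g)[1]])
  }

  if (is.null(strains)) {
    strains <- data.frame(strain_id = sort(unique(pheno$strain)),
                          stringsAsFactors = FALSE)
    strains$label <- strains$strain_id
  }
  strains <- as.data.frame(strains)
  strains$strain_id <- as.character(strains$strain_id)
  if (!all(pheno$strain %in% strains$strain_id)) {
    stop("strain metadata missing for: ",
         paste(setdiff(pheno$strain, strains$strain_id), collapse = ", "))
  }

  structure(list(map = map, geno = geno, pheno = pheno, strains = strains),
            class = "congenic_panel")
}

#' @export
print.congenic_panel <- function(x, ...) {
  cat(sprintf("<congenic_panel: %d mice, %d strains, %d markers (%s)>\n",
              nrow(x$pheno), length(unique(x$pheno$strain)), nrow(x$map),
              paste(unique(x$map$chrom), collapse = ",")))
  n_x <- sum(x$geno == "X")
  cat(sprintf("  missing genotypes: %d (%.2f%%); excluded mice: %d\n",
              n_x, 100 * n_x / length(x$geno), sum(x$pheno$excluded)))
  invisible(x)
}

#' Read a congenic panel from its three input files
#'
#' File conventions: the marker map is a TSV with columns `marker_id`,
#' `chrom`, `pos_bp`; the genotype table is a TSV whose first column is
#' `mouse_id` and remaining columns are markers (cells in `{A, H, X}`);
#' the phenotype table is a CSV with columns `mouse_id`, `strain`,
#' `depot_g`, `bw_g`, `age_d`, `excluded`, `reason`.
#'
#' @param map_path,genotype_path,phenotype_path file paths.
#' @return A validated [congenic_panel()].
#' @export
read_panel <- function(map_path, genotype_path, phenotype_path) {
  for (p in c(map_path, genotype_path, phenotype_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  g <- utils::read.delim(genotype_path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (names(g)[1] != "mouse_id") stop("genotype table must start with a mouse_id column")
  if (anyDuplicated(g$mouse_id)) {
    stop("duplicate mouse_id in genotype table: ",
         paste(unique(g$mouse_id[duplicated(g$mouse_id)]), collapse = ", "))
  }
  geno <- as.matrix(g[, -1, drop = FALSE])
  rownames(geno) <- g$mouse_id
  pheno <- utils::read.csv(phenotype_path, stringsAsFactors = FALSE)
  pheno$reason[is.na(pheno$reason)] <- ""
  if (!identical(colnames(geno), as.character(map$marker_id))) {
    stop("genotype columns do not match marker map order")
  }
  panel <- congenic_panel(map, geno, pheno)
  message(sprintf("read_panel: %d mice x %d markers", nrow(panel$pheno),
                  nrow(panel$map)))
  panel
}

#' Donor region of one mouse
#'
#' Converts a mouse's genotype vector into the set of donor-derived intervals:
#' one interval per maximal run of `H` markers, bounded at the observed marker
#' positions (inner-bound convention; the true recombination breakpoint lies
#' between the last `H` and the first flanking `A` marker).
#'
#' @param genotypes character vector of codes over the map's markers.
#' @param map marker map data.frame (single chromosome).
#' @param na_policy `"error"` (default) refuses residual missing codes and
#'   instructs to impute first; `"omit"` drops missing markers from the run
#'   scan, leaving boundaries at the nearest observed `H` marker.
#' @return An [interval_set()].
#' @export
donor_region <- function(genotypes, map, na_policy = c("error", "omit")) {
  na_policy <- match.arg(na_policy)
  if (length(genotypes) != nrow(map)) {
    stop("genotype vector length does not match marker map")
  }
  pos <- map$pos_bp
  if (any(genotypes == "X")) {
    if (na_policy == "error") {
      stop("residual missing genotypes (X); run impute_genotypes() first ",
           "or use na_policy = \"omit\"")
    }
    keep <- genotypes != "X"
    genotypes <- genotypes[keep]
    pos <- pos[keep]
  }
  if (length(genotypes) == 0 || !any(genotypes == "H")) {
    return(interval_set())
  }
  r <- rle(genotypes == "H")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  h <- which(r$values)
  interval_set(pos[starts[h]], pos[ends[h]])
}

#' Donor regions for every mouse in a panel
#'
#' @param panel a [congenic_panel()].
#' @inheritParams donor_region
#' @return Named list of [interval_set()] objects, one per mouse.
#' @export
panel_donor_regions <- function(panel, na_policy = c("error", "omit")) {
  na_policy <- match.arg(na_policy)
  out <- lapply(seq_len(nrow(panel$geno)), function(i) {
    donor_region(panel$geno[i, ], panel$map, na_policy = na_policy)
  })
  names(out) <- rownames(panel$geno)
  out
}

#' Per-strain donor-region summary
#'
#' Determines each strain's modal full-length donor region (over its donor
#' mice) and flags each donor mouse as full-length or partial. Mice whose
#' donor region is empty are hosts.
#'
#' @param panel a [congenic_panel()].
#' @param na_policy passed to [donor_region()].
#' @return list with `strain_regions` (named list of `interval_set`, one per
#'   strain with any donor mice) and `mouse_status` (data.frame: `mouse_id`,
#'   `strain`, `is_donor`, `is_full`).
#' @export
strain_donor_summary <- function(panel, na_policy = "omit") {
  regions <- panel_donor_regions(panel, na_policy = na_policy)
  is_donor <- !vapply(regions, ivs_is_empty, logical(1))
  strain_regions <- list()
  for (s in unique(panel$pheno$strain)) {
    idx <- which(panel$pheno$strain == s & is_donor)
    if (length(idx) == 0) next
    keys <- vapply(regions[idx], format, character(1))
    modal <- names(sort(table(keys), decreasing = TRUE))[1]
    strain_regions[[s]] <- regions[[idx[match(modal, keys)]]]
  }
  is_full <- vapply(seq_along(regions), function(i) {
    s <- panel$pheno$strain[i]
    is_donor[i] && !is.null(strain_regions[[s]]) &&
      ivs_equal(regions[[i]], strain_regions[[s]])
  }, logical(1))
  list(strain_regions = strain_regions,
       mouse_status = data.frame(mouse_id = panel$pheno$mouse_id,
                                 strain = panel$pheno$strain,
                                 is_donor = unname(is_donor),
                                 is_full = unname(is_full),
                                 stringsAsFactors = FALSE))
}
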