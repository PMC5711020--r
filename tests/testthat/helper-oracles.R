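# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: interval sets become integer membership vectors, OLS is
# solved from the normal equations, spanning trees are enumerated, and the
# multi-QTL consistency search enumerates all 3^B sign assignments.

# ---- interval sets as membership over [1, max_bp] ----

bf_members <- function(ivs, max_bp = 1000) {
  m <- rep(FALSE, max_bp)
  for (i in seq_along(ivs$start)) m[ivs$start[i]:ivs$end[i]] <- TRUE
  m
}

bf_from_members <- function(m) {
  idx <- which(m)
  if (length(idx) == 0) return(list(start = integer(), end = integer()))
  brk <- c(0, which(diff(idx) > 1), length(idx))
  list(start = idx[brk[-length(brk)] + 1], end = idx[brk[-1]])
}

expect_ivs_matches_members <- function(ivs, m) {
  ref <- bf_from_members(m)
  expect_equal(as.integer(ivs$start), as.integer(ref$start))
  expect_equal(as.integer(ivs$end), as.integer(ref$end))
}

random_ivs <- function(max_bp = 1000, max_n = 4) {
  n <- sample(0:max_n, 1)
  if (n == 0) return(interval_set())
  s <- sample(max_bp, n, replace = TRUE)
  w <- sample(0:(max_bp / 5), n, replace = TRUE)
  interval_set(s, pmin(s + w, max_bp))
}

# ---- donor region by direct run-length scan ----

bf_donor_region <- function(genotypes, pos) {
  runs <- list()
  i <- 1
  while (i <= length(genotypes)) {
    if (genotypes[i] == "H") {
      j <- i
      while (j < length(genotypes) && genotypes[j + 1] == "H") j <- j + 1
      runs[[length(runs) + 1]] <- c(pos[i], pos[j])
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# ---- OLS from the normal equations ----

bf_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# ---- exhaustive minimum spanning tree (n <= 7 nodes) ----

bf_mst_weight <- function(w) {
  # w: symmetric weight matrix; enumerate all (n-1)-edge subsets
  n <- nrow(w)
  edges <- which(upper.tri(w), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(edges), n - 1, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (k in sel) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(w[edges[sel, , drop = FALSE]]))
  }
  best
}

# ---- exhaustive multi-QTL consistency over all 3^B assignments ----
# comparisons: list of list(child_bins=, parent_bins=, verdict=)
bf_qtl_models <- function(n_bins, comparisons, bin_len) {
  states <- expand.grid(rep(list(c(0, 1, -1)), n_bins))
  consistent <- list()
  for (r in seq_len(nrow(states))) {
    a <- as.numeric(states[r, ])
    ok <- TRUE
    for (cmp in comparisons) {
      eff <- c(a[cmp$child_bins], -a[cmp$parent_bins])
      eff <- eff[eff != 0]
      if (cmp$verdict == "greater") {
        if (!any(eff == 1)) { ok <- FALSE; break }
      } else if (cmp$verdict == "less") {
        if (!any(eff == -1)) { ok <- FALSE; break }
      } else {
        if (length(eff) > 0 && !(any(eff == 1) && any(eff == -1))) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) consistent[[length(consistent) + 1]] <- a
  }
  n_active <- vapply(consistent, function(a) sum(a != 0), numeric(1))
  minimal <- consistent[n_active == min(n_active)]
  tot <- vapply(minimal, function(a) sum(bin_len[a != 0]), numeric(1))
  minimal[tot == min(tot)]
}

# ---- small hand-built panels ----

toy_map <- function(pos_mb, chrom = "9") {
  data.frame(marker_id = sprintf("m%02d", seq_along(pos_mb)), chrom = chrom,
             pos_bp = pos_mb * 1e6, stringsAsFactors = FALSE)
}

toy_panel <- function(geno_rows, pos_mb, strain = NULL, depot = NULL,
                      bw = NULL) {
  n <- length(geno_rows)
  geno <- do.call(rbind, geno_rows)
  rownames(geno) <- sprintf("M%03d", seq_len(n))
  if (is.null(strain)) strain <- rep("s1", n)
  if (is.null(depot)) depot <- rep(0.5, n)
  if (is.null(bw)) bw <- rep(31, n)
  pheno <- data.frame(mouse_id = rownames(geno), strain = strain,
                      depot_g = depot, bw_g = bw, age_d = 180L,
                      excluded = FALSE, reason = "", stringsAsFactors = FALSE)
  congenic_panel(toy_map(pos_mb), geno, pheno)
}

# comparison_set built from stated verdicts over given regions (noiseless)
manual_comparisons <- function(regions, edges, verdicts, host_id = "host") {
  nodes <- c(list(interval_set()), regions)
  names(nodes)[1] <- host_id
  cc <- data.frame(child = edges[, 1], parent = edges[, 2], n_1 = 30L,
                   n_2 = 30L, mean_1 = NA_real_, mean_2 = NA_real_,
                   p = ifelse(verdicts == "equal", 0.5, 0.001),
                   verdict = verdicts, anomaly = FALSE,
                   stringsAsFactors = FALSE)
  attr(cc, "difference_regions") <- lapply(seq_len(nrow(cc)), function(i) {
    ivs_symdiff(nodes[[cc$child[i]]], nodes[[cc$parent[i]]])
  })
  structure(list(comparisons = cc, alpha = 0.05, nodes = nodes,
                 host_id = host_id), class = "comparison_set")
}

# expected verdicts for a graph under planted additive QTLs
truth_verdicts <- function(graph, qtls) {
  net <- function(r) sum(qtls$effect * ivs_covers(r, qtls$pos_bp))
  vapply(seq_len(nrow(graph$traversal)), function(i) {
    d <- net(graph$nodes[[graph$traversal$child[i]]]) -
      net(graph$nodes[[graph$traversal$parent[i]]])
    if (d > 0) "greater" else if (d < 0) "less" else "equal"
  }, character(1))
}
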