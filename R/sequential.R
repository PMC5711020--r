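#' Minimum spanning tree over donor-region similarity
#'
#' Builds the complete graph whose nodes are the congenic strains plus a
#' synthetic host node (empty donor region) and whose edge weights are the
#' base-pair length of the symmetric difference between the two nodes' donor
#' regions, then extracts the minimum spanning tree. This metric makes
#' nested neighbors adjacent and disjoint fragments distant, which is what
#' orders the sequential comparisons. Kruskal's algorithm is used with a
#' deterministic tie-break on (weight, lexicographic node pair). Strains
#' with literally identical donor regions (a zero-weight edge) are merged
#' into one node with a warning. The traversal order is breadth-first from
#' the host node, visiting children in ascending edge weight.
#'
#' @param strain_regions named list of [interval_set()] donor regions, one
#'   per strain (full-length representative).
#' @param host_id node id for the synthetic host (default `"host"`).
#' @return An object of class `strain_graph`: `nodes` (named list of
#'   regions, merged strains joined by `+`), `edges` (MST edge data.frame
#'   `from`, `to`, `weight`), and `traversal` (data.frame `child`,
#'   `parent`, `weight` in comparison order).
#' @export
build_mst <- function(strain_regions, host_id = "host") {
  if (length(strain_regions) < 1) stop("need at least one strain")
  if (host_id %in% names(strain_regions)) {
    stop("host_id clashes with a strain id")
  }
  # merge duplicate regions
  sig <- vapply(strain_regions, format, character(1))
  nodes <- list()
  nodes[[host_id]] <- interval_set()
  for (k in unique(sig)) {
    ids <- sort(names(strain_regions)[sig == k])
    if (length(ids) > 1) {
      warning("strains with identical donor regions merged into one node: ",
              paste(ids, collapse = "+"))
    }
    if (k == "{}") {
      warning("strain(s) with empty donor region merged into the host node: ",
              paste(ids, collapse = "+"))
      next
    }
    nodes[[paste(ids, collapse = "+")]] <- strain_regions[[ids[1]]]
  }
  ids <- names(nodes)
  n <- length(ids)
  if (n < 2) stop("need at least 2 distinct nodes")
  edges <- NULL
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- sort(c(ids[i], ids[j]))
      edges <- rbind(edges, data.frame(
        from = a[1], to = a[2],
        weight = ivs_length(ivs_symdiff(nodes[[ids[i]]], nodes[[ids[j]]])),
        stringsAsFactors = FALSE))
    }
  }
  edges <- edges[order(edges$weight, edges$from, edges$to), , drop = FALSE]
  # Kruskal with union-find
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  mst <- NULL
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$from[i]); rb <- find(edges$to[i])
    if (ra != rb) {
      parent[[ra]] <- rb
      mst <- rbind(mst, edges[i, , drop = FALSE])
      if (nrow(mst) == n - 1) break
    }
  }
  # BFS from host, children in ascending edge weight (then lexicographic)
  adj <- function(node) {
    e <- mst[mst$from == node | mst$to == node, , drop = FALSE]
    nb <- ifelse(e$from == node, e$to, e$from)
    o <- order(e$weight, nb)
    data.frame(node = nb[o], weight = e$weight[o], stringsAsFactors = FALSE)
  }
  visited <- host_id
  queue <- host_id
  traversal <- NULL
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    nb <- adj(cur)
    for (k in seq_len(nrow(nb))) {
      if (!nb$node[k] %in% visited) {
        visited <- c(visited, nb$node[k])
        queue <- c(queue, nb$node[k])
        traversal <- rbind(traversal, data.frame(
          child = nb$node[k], parent = cur, weight = nb$weight[k],
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(mst) <- NULL
  structure(list(nodes = nodes, edges = mst, traversal = traversal,
                 host_id = host_id),
            class = "strain_graph")
}

#' @export
print.strain_graph <- function(x, ...) {
  cat(sprintf("<strain_graph: %d nodes, MST weight %s bp>\n",
              length(x$nodes), format(sum(x$edges$weight), big.mark = ",")))
  for (i in seq_len(nrow(x$traversal))) {
    cat(sprintf("  %s -> %s (%s bp)\n", x$traversal$parent[i],
                x$traversal$child[i],
                format(x$traversal$weight[i], big.mark = ",")))
  }
  invisible(x)
}

.node_strains <- function(node_id) strsplit(node_id, "+", fixed = TRUE)[[1]]

#' Ordered pairwise strain comparisons along the MST
#'
#' Fits one joint model of the prepared phenotype (body weight covariate,
#' then a group factor with one level per strain node -- full-length donor
#' mice only -- plus the pooled host group of all homozygous littermates),
#' then runs a Fisher's LSD contrast for every MST edge in traversal order.
#' Each comparison's verdict is `greater`, `less` or `equal` (first group =
#' the child node), with `equal` meaning p >= alpha. The difference region
#' is the symmetric difference of the two donor regions; an empty
#' difference region with a significant verdict is flagged as anomalous.
#'
#' @param graph a [build_mst()] result.
#' @param panel a prepared [congenic_panel()].
#' @param summary optional precomputed [strain_donor_summary()].
#' @param alpha LSD significance level (default 0.05).
#' @return An object of class `comparison_set`: data.frame `comparisons`
#'   (child, parent, n_1, n_2, mean_1, mean_2, p, verdict, anomaly) with the
#'   per-edge difference regions in `attr(, "difference_regions")`, plus the
#'   joint `fit` and the group assignment.
#' @export
run_comparisons <- function(graph, panel, summary = NULL, alpha = 0.05) {
  if (is.null(panel$pheno$y)) {
    stop("panel has no prepared phenotype; run prepare_phenotypes() first")
  }
  if (is.null(summary)) summary <- strain_donor_summary(panel)
  st <- summary$mouse_status
  group <- rep(NA_character_, nrow(st))
  group[!st$is_donor] <- graph$host_id
  for (node in setdiff(names(graph$nodes), graph$host_id)) {
    in_node <- st$strain %in% .node_strains(node) & st$is_full
    group[in_node] <- node
  }
  use <- !is.na(group)
  ph <- panel$pheno[match(st$mouse_id[use], panel$pheno$mouse_id), ,
                    drop = FALSE]
  d <- data.frame(y = ph$y, bw = ph$bw_g, group = factor(group[use]),
                  stringsAsFactors = FALSE)
  fit <- fit_glm(d, "y", c("bw", "group"))
  am <- adjusted_means(fit, "group")
  nn <- table(d$group)
  out <- NULL
  diffs <- list()
  for (i in seq_len(nrow(graph$traversal))) {
    child <- graph$traversal$child[i]; par <- graph$traversal$parent[i]
    dr <- ivs_symdiff(graph$nodes[[child]], graph$nodes[[par]])
    n1 <- if (child %in% names(nn)) nn[[child]] else 0L
    n2 <- if (par %in% names(nn)) nn[[par]] else 0L
    if (n1 < 2 || n2 < 2) {
      warning("comparison ", child, " vs ", par, " skipped: group below 2 mice")
      out <- rbind(out, data.frame(child = child, parent = par,
                                   n_1 = n1, n_2 = n2, mean_1 = NA_real_,
                                   mean_2 = NA_real_, p = NA_real_,
                                   verdict = "skipped", anomaly = FALSE,
                                   stringsAsFactors = FALSE))
      diffs[[length(diffs) + 1]] <- dr
      next
    }
    ct <- lsd_contrast(am[[child]], am[[par]], n1, n2, fit$mse,
                       fit$df_residual)
    verdict <- if (ct$p >= alpha) "equal" else if (ct$diff > 0) "greater" else "less"
    anomaly <- ivs_is_empty(dr) && verdict != "equal"
    if (anomaly) {
      warning("significant difference between nodes with identical donor regions: ",
              child, " vs ", par)
    }
    out <- rbind(out, data.frame(child = child, parent = par, n_1 = n1,
                                 n_2 = n2, mean_1 = am[[child]],
                                 mean_2 = am[[par]], p = ct$p,
                                 verdict = verdict, anomaly = anomaly,
                                 stringsAsFactors = FALSE))
    diffs[[length(diffs) + 1]] <- dr
  }
  rownames(out) <- NULL
  attr(out, "difference_regions") <- diffs
  structure(list(comparisons = out, fit = fit, alpha = alpha,
                 nodes = graph$nodes, host_id = graph$host_id),
            class = "comparison_set")
}

#' @export
print.comparison_set <- function(x, ...) {
  cc <- x$comparisons
  sym <- c(greater = ">", less = "<", equal = "=", skipped = "?")
  cat(sprintf("<comparison_set: %d ordered comparisons (alpha = %.2f)>\n",
              nrow(cc), x$alpha))
  for (i in seq_len(nrow(cc))) {
    cat(sprintf("  %s %s %s  (p = %s)\n", cc$child[i], sym[[cc$verdict[i]]],
                cc$parent[i],
                if (is.na(cc$p[i])) "NA" else format.pval(cc$p[i], digits = 3)))
  }
  invisible(x)
}

# atomic bins delimited by the union of all regions' endpoints
.atomic_bins <- function(regions) {
  cuts <- sort(unique(unlist(lapply(regions, function(r) {
    if (ivs_is_empty(r)) numeric() else c(r$start, r$end + 1)
  }))))
  if (length(cuts) < 2) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  bins <- data.frame(start = cuts[-length(cuts)], end = cuts[-1] - 1)
  # keep bins lying inside at least one region
  mid <- (bins$start + bins$end) / 2
  inside <- vapply(seq_along(mid), function(i) {
    any(vapply(regions, function(r) ivs_covers(r, mid[i]), logical(1)))
  }, logical(1))
  bins[inside, , drop = FALSE]
}

# per-comparison effective-sign machinery shared with the tests' oracle is
# intentionally NOT shared: the oracle re-derives it independently.
.comparison_bins <- function(comparisons, nodes, bins) {
  diffs <- attr(comparisons, "difference_regions")
  mid <- (bins$start + bins$end) / 2
  lapply(seq_len(nrow(comparisons)), function(i) {
    child_r <- nodes[[comparisons$child[i]]]
    in_child <- ivs_covers(child_r, mid)
    in_diff <- ivs_covers(diffs[[i]], mid)
    list(child_only = which(in_diff & in_child),
         parent_only = which(in_diff & !in_child))
  })
}

.check_assignment <- function(active, signs, cmp_bins, verdicts) {
  masked <- logical(length(verdicts))
  for (i in seq_along(verdicts)) {
    v <- verdicts[i]
    if (v == "skipped") next
    cb <- cmp_bins[[i]]
    eff <- c(signs[match(intersect(active, cb$child_only), active)],
             -signs[match(intersect(active, cb$parent_only), active)])
    if (v == "greater") {
      if (!any(eff == 1)) return(NULL)
    } else if (v == "less") {
      if (!any(eff == -1)) return(NULL)
    } else { # equal
      if (length(eff) > 0) {
        if (!(any(eff == 1) && any(eff == -1))) return(NULL)
        masked[i] <- TRUE
      }
    }
  }
  masked
}

.merge_bins <- function(bins, active, signs) {
  if (length(active) == 0) {
    return(data.frame(start = numeric(), end = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  }
  o <- order(bins$start[active])
  act <- active[o]; sg <- signs[o]
  qs <- bins$start[act[1]]; qe <- bins$end[act[1]]; qsg <- sg[1]
  out <- NULL
  for (k in seq_along(act)[-1]) {
    if (bins$start[act[k]] == qe + 1 && sg[k] == qsg) {
      qe <- bins$end[act[k]]
    } else {
      out <- rbind(out, data.frame(start = qs, end = qe,
                                   sign = if (qsg > 0) "+" else "-",
                                   stringsAsFactors = FALSE))
      qs <- bins$start[act[k]]; qe <- bins$end[act[k]]; qsg <- sg[k]
    }
  }
  rbind(out, data.frame(start = qs, end = qe,
                        sign = if (qsg > 0) "+" else "-",
                        stringsAsFactors = FALSE))
}

#' Infer the minimal multi-QTL model from ordered comparisons
#'
#' Partitions the chromosome into atomic bins delimited by every donor-region
#' boundary, then searches assignments of `{absent, +, -}` to bins in
#' increasing number of active bins. An assignment is consistent when (i)
#' every significant comparison has at least one active bin of the
#' verdict-matching effective sign inside its difference region (a bin
#' carried by the first group keeps its sign; one carried by the second
#' group counts with the opposite sign), and (ii) every non-significant
#' comparison's difference region contains either no active bins or active
#' bins of both effective signs -- allowing linked QTLs of opposite sign to
#' cancel, which such comparisons are then flagged as masking. Among
#' consistent assignments with the fewest active bins, those of minimal
#' total active length are reported; adjacent same-sign bins merge into one
#' QTL interval.
#'
#' @param comparisons a [run_comparisons()] result.
#' @param max_qtls give up after this many active bins (default 6).
#' @return An object of class `qtl_model`: `models`, a list of co-minimal
#'   models (each with `qtls` data.frame `start`, `end`, `sign`; active
#'   `bins`; `masked` comparison indices; `support` significant-comparison
#'   indices per QTL), plus the bin partition and the comparison table.
#' @export
infer_qtl_model <- function(comparisons, max_qtls = 6) {
  cc <- comparisons$comparisons
  nodes <- comparisons$nodes
  bins <- .atomic_bins(nodes)
  cmp_bins <- .comparison_bins(cc, nodes, bins)
  candidates <- sort(unique(unlist(lapply(cmp_bins, function(b) {
    c(b$child_only, b$parent_only)
  }))))
  verdicts <- cc$verdict
  found <- list()
  for (k in 0:min(max_qtls, length(candidates))) {
    combos <- if (k == 0) list(integer()) else
      utils::combn(candidates, k, simplify = FALSE)
    sign_grids <- if (k == 0) list(integer()) else
      as.matrix(expand.grid(rep(list(c(1, -1)), k)))
    for (act in combos) {
      if (k == 0) {
        m <- .check_assignment(integer(), integer(), cmp_bins, verdicts)
        if (!is.null(m)) {
          found[[length(found) + 1]] <- list(active = integer(),
                                             signs = integer(), masked = m)
        }
        next
      }
      for (r in seq_len(nrow(sign_grids))) {
        sg <- as.integer(sign_grids[r, ])
        m <- .check_assignment(act, sg, cmp_bins, verdicts)
        if (!is.null(m)) {
          found[[length(found) + 1]] <- list(active = act, signs = sg,
                                             masked = m)
        }
      }
    }
    if (length(found) > 0) break
  }
  if (length(found) == 0) {
    conf <- which(verdicts %in% c("greater", "less"))
    stop("no consistent QTL model with up to ", max_qtls,
         " QTLs; significant comparisons involved: ",
         paste(paste(cc$child[conf], cc$parent[conf], sep = " vs "),
               collapse = "; "))
  }
  tot_len <- vapply(found, function(f) {
    if (length(f$active) == 0) 0 else
      sum(bins$end[f$active] - bins$start[f$active] + 1)
  }, numeric(1))
  found <- found[tot_len == min(tot_len)]
  models <- lapply(found, function(f) {
    qtls <- .merge_bins(bins, f$active, f$signs)
    support <- lapply(seq_len(nrow(qtls)), function(q) {
      reg <- interval_set(qtls$start[q], qtls$end[q])
      which(verdicts %in% c("greater", "less") &
              vapply(seq_along(cmp_bins), function(i) {
                idx <- c(cmp_bins[[i]]$child_only, cmp_bins[[i]]$parent_only)
                length(idx) > 0 &&
                  any(ivs_covers(reg, (bins$start[idx] + bins$end[idx]) / 2))
              }, logical(1)))
    })
    list(qtls = qtls, bins = data.frame(start = bins$start[f$active],
                                        end = bins$end[f$active],
                                        sign = f$signs),
         masked = which(f$masked), support = support)
  })
  structure(list(models = models, bins = bins, comparisons = cc,
                 n_qtls = if (length(models) == 0) 0L else
                   nrow(models[[1]]$qtls)),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("<qtl_model: %d co-minimal model(s) with %d QTL(s)>\n",
              length(x$models), x$n_qtls))
  for (m in seq_along(x$models)) {
    q <- x$models[[m]]$qtls
    cat(sprintf(" model %d:\n", m))
    for (i in seq_len(nrow(q))) {
      cat(sprintf("   QTL%d %s: %s-%s\n", i, q$sign[i],
                  format(q$start[i], big.mark = ","),
                  format(q$end[i], big.mark = ",")))
    }
    if (length(x$models[[m]]$masked) > 0) {
      cat("   masked comparisons:",
          paste(x$models[[m]]$masked, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Refine a wide QTL interval around an external anchor marker
#'
#' Replaces a poorly localized (wide) QTL interval with the anchor marker's
#' position plus/minus a flanking distance, clipped to the original
#' interval. Used when an external mapping result (e.g., an earlier
#' intercross) pins the locus to a marker inside a broad congenic interval.
#'
#' @param qtls data.frame with columns `start`, `end`, `sign` (as in a
#'   `qtl_model` entry).
#' @param anchor_bp anchor marker position (bp); must fall inside the
#'   interval being refined.
#' @param flank_mb total width in Mb of the flanking region centered on the
#'   anchor (default 10, i.e. anchor +/- 5 Mb).
#' @param min_width_mb only intervals at least this wide are eligible
#'   (default 20).
#' @return The `qtls` data.frame with the refined interval and a `refined`
#'   logical column recording provenance.
#' @export
refine_qtl4 <- function(qtls, anchor_bp, flank_mb = 10, min_width_mb = 20) {
  width <- qtls$end - qtls$start + 1
  wide <- which(width > min_width_mb * 1e6)
  if (length(wide) == 0) stop("no QTL interval wider than ", min_width_mb, " Mb")
  hit <- wide[qtls$start[wide] <= anchor_bp & anchor_bp <= qtls$end[wide]]
  if (length(hit) == 0) stop("anchor position lies outside every wide QTL interval")
  i <- hit[1]
  qtls$refined <- FALSE
  half <- flank_mb * 1e6 / 2
  new_start <- max(qtls$start[i], anchor_bp - half)
  new_end <- min(qtls$end[i], anchor_bp + half)
  qtls$start[i] <- new_start
  qtls$end[i] <- new_end
  qtls$refined[i] <- TRUE
  qtls
}

#' Per-QTL genotype effect table
#'
#' For each QTL interval, selects the panel marker nearest the interval
#' midpoint and reports least-squares means with 95% confidence limits for
#' the two genotype groups at that marker (body weight as covariate), the
#' per-locus effect display that accompanies a multi-QTL model. The host
#' group is the homozygous littermates carrying no donor region at all; the
#' donor group is drawn
#' only from strains that isolate the locus as far as the panel allows --
#' among strains whose donor region covers the marker, those covering the
#' fewest other QTL intervals. Without this restriction a locus whose
#' allele lowers the trait would be hidden by carriers of linked raising
#' alleles.
#'
#' @param panel a prepared [congenic_panel()].
#' @param qtls data.frame with columns `start`, `end` (and optionally
#'   `sign`).
#' @param summary optional precomputed [strain_donor_summary()].
#' @return data.frame: one row per QTL x genotype with `marker_id`,
#'   `genotype`, `n`, `lsmean`, `lower`, `upper`.
#' @export
qtl_effect_table <- function(panel, qtls, summary = NULL) {
  if (is.null(summary)) summary <- strain_donor_summary(panel)
  st <- summary$mouse_status
  out <- NULL
  for (i in seq_len(nrow(qtls))) {
    mid <- (qtls$start[i] + qtls$end[i]) / 2
    j <- which.min(abs(panel$map$pos_bp - mid))
    pos_j <- panel$map$pos_bp[j]
    covering <- names(summary$strain_regions)[vapply(
      summary$strain_regions, function(r) ivs_covers(r, pos_j), logical(1))]
    others <- qtls[-i, , drop = FALSE]
    n_other <- vapply(covering, function(s) {
      r <- summary$strain_regions[[s]]
      sum(vapply(seq_len(nrow(others)), function(k) {
        !ivs_is_empty(ivs_intersect(r, interval_set(others$start[k],
                                                    others$end[k])))
      }, logical(1)))
    }, numeric(1))
    chosen <- covering[n_other == min(n_other)]
    g <- panel$geno[panel$pheno$mouse_id, j]
    strain <- panel$pheno$strain
    idx <- match(panel$pheno$mouse_id, st$mouse_id)
    donor_ok <- st$is_full[idx] & strain %in% chosen
    # host group = homozygous littermates without any donor region
    use <- (!st$is_donor[idx] & g == "A") | (g == "H" & donor_ok)
    d <- data.frame(y = panel$pheno$y[use], bw = panel$pheno$bw_g[use],
                    genotype = factor(g[use], c("A", "H")))
    fit <- stats::lm(y ~ bw + genotype, data = d)
    nd <- data.frame(bw = mean(d$bw), genotype = factor(c("A", "H"), c("A", "H")))
    ci <- stats::predict(fit, nd, interval = "confidence", level = 0.95)
    out <- rbind(out, data.frame(qtl = i, marker_id = panel$map$marker_id[j],
                                 genotype = c("A", "H"),
                                 n = as.vector(table(d$genotype)),
                                 lsmean = ci[, "fit"], lower = ci[, "lwr"],
                                 upper = ci[, "upr"],
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
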