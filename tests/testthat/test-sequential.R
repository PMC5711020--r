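mb <- function(s, e) interval_set(s * 1e6, e * 1e6)

test_that("nested donor regions chain outward from the host on the MST", {
  g <- build_mst(list(a = mb(1, 10), b = mb(1, 20), c = mb(1, 30)))
  expect_equal(g$traversal$child, c("a", "b", "c"))
  expect_equal(g$traversal$parent, c("host", "a", "b"))
})

test_that("disjoint donor branches both attach at the host", {
  g <- build_mst(list(a = mb(1, 10), b = mb(50, 60)))
  expect_setequal(g$traversal$parent, "host")
  g1 <- build_mst(list(only = mb(5, 15)))
  expect_equal(nrow(g1$edges), 1)
})

test_that("duplicate donor regions merge into one node with a warning", {
  expect_warning(g <- build_mst(list(a = mb(1, 10), b = mb(1, 10),
                                     c = mb(1, 30))),
                 "identical donor regions")
  expect_true("a+b" %in% names(g$nodes))
  expect_equal(length(g$nodes), 3)  # host, a+b, c
})

test_that("MST weight equals the exhaustive minimum and igraph agrees", {
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    regs <- lapply(seq_len(n), function(i) random_ivs(200, 3))
    names(regs) <- letters[seq_len(n)]
    regs <- regs[!vapply(regs, ivs_is_empty, logical(1))]
    sig <- vapply(regs, format, character(1))
    regs <- regs[!duplicated(sig)]
    if (length(regs) < 2) next
    g <- suppressWarnings(build_mst(regs))
    ids <- names(g$nodes)
    k <- length(ids)
    w <- matrix(0, k, k)
    for (i in 1:k) for (j in 1:k) {
      w[i, j] <- ivs_length(ivs_symdiff(g$nodes[[ids[i]]], g$nodes[[ids[j]]]))
    }
    expect_equal(sum(g$edges$weight), bf_mst_weight(w))
    if (requireNamespace("igraph", quietly = TRUE)) {
      ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                                weighted = TRUE)
      im <- igraph::mst(ig)
      expect_equal(sum(g$edges$weight), sum(igraph::E(im)$weight))
    }
  }
})

test_that("comparisons detect a planted effect in the child's extra segment", {
  cfg <- sim_config(n_per_genotype = 20,
                    marker_pos_bp = c(10e6, 20e6, 30e6, 40e6),
                    strains = list(p = interval_set(10e6, 20e6),
                                   q = interval_set(10e6, 40e6)),
                    qtls = data.frame(qtl = "Q", pos_bp = 35e6, effect = 1),
                    partial_prob = 0, missing_rate = 0, exclusion_rate = 0,
                    seed = 72)
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  panel$pheno$y <- log(panel$pheno$depot_g)
  s <- strain_donor_summary(panel)
  g <- build_mst(s$strain_regions)
  cmp <- run_comparisons(g, panel, summary = s)
  cc <- cmp$comparisons
  expect_equal(cc$verdict[cc$child == "q" & cc$parent == "p"], "greater")
  expect_equal(cc$verdict[cc$child == "p"], "equal")  # p carries no QTL
})

test_that("minimal model inference matches the stated toy scenarios", {
  # only the outermost nested strain differs from host: one QTL in its
  # private distal segment
  regs <- list(a = mb(1, 10), b = mb(1, 20), c = mb(1, 30))
  cs <- manual_comparisons(regs,
                           cbind(c("a", "b", "c"), c("host", "a", "b")),
                           c("equal", "equal", "greater"))
  m <- infer_qtl_model(cs)
  expect_equal(m$n_qtls, 1)
  expect_equal(m$models[[1]]$qtls$sign, "+")
  expect_gte(m$models[[1]]$qtls$start, 20e6)

  # a strain spanning two bins is silent while its sub-strain is elevated:
  # opposing linked QTLs, flagged as masked
  regs2 <- list(B1 = mb(10, 30), B2 = mb(10, 20))
  cs2 <- manual_comparisons(regs2,
                            cbind(c("B1", "B2"), c("host", "host")),
                            c("equal", "greater"))
  m2 <- infer_qtl_model(cs2)
  expect_equal(m2$n_qtls, 2)
  expect_setequal(m2$models[[1]]$qtls$sign, c("+", "-"))
  plus <- m2$models[[1]]$qtls[m2$models[[1]]$qtls$sign == "+", ]
  expect_lte(plus$end, 20e6 + 1)
  expect_equal(m2$models[[1]]$masked, 1L)

  # all comparisons equal: empty model
  cs3 <- manual_comparisons(regs, cbind(c("a", "b", "c"), c("host", "a", "b")),
                            rep("equal", 3))
  m3 <- infer_qtl_model(cs3)
  expect_equal(m3$n_qtls, 0)

  # impossible verdicts: no consistent model
  cs4 <- manual_comparisons(list(a = mb(1, 10)), cbind("a", "host"),
                            "greater")
  cs4$comparisons$verdict <- "greater"
  # duplicate the edge with contradictory direction
  cc <- cs4$comparisons
  cc2 <- rbind(cc, transform(cc, verdict = "less"))
  attr(cc2, "difference_regions") <-
    c(attr(cs4$comparisons, "difference_regions"),
      attr(cs4$comparisons, "difference_regions"))
  cs4$comparisons <- cc2
  expect_error(infer_qtl_model(cs4), "no consistent QTL model")
})

test_that("inference agrees with exhaustive sign-assignment enumeration", {
  set.seed(73)
  for (rep in 1:8) {
    # random nested/overlapping regions over a 100-Mb toy chromosome
    n <- sample(3:5, 1)
    regs <- lapply(seq_len(n), function(i) {
      s <- sample(seq(1, 80, by = 10), 1)
      e <- s + sample(seq(9, 49, by = 10), 1)
      interval_set(s * 1e6, min(e, 100) * 1e6)
    })
    names(regs) <- letters[seq_len(n)]
    sig <- vapply(regs, format, character(1))
    regs <- regs[!duplicated(sig)]
    if (length(regs) < 2) next
    g <- suppressWarnings(build_mst(regs))
    verdicts <- sample(c("greater", "less", "equal"),
                       nrow(g$traversal), replace = TRUE)
    cs <- manual_comparisons(regs,
                             as.matrix(g$traversal[, c("child", "parent")]),
                             verdicts)
    # independent bin derivation and consistency enumeration
    cuts <- sort(unique(unlist(lapply(regs, function(r) c(r$start, r$end + 1)))))
    bins <- cbind(cuts[-length(cuts)], cuts[-1] - 1)
    mid <- rowMeans(bins)
    inside <- vapply(seq_along(mid), function(i) {
      any(vapply(regs, function(r) ivs_covers(r, mid[i]), logical(1)))
    }, logical(1))
    bins <- bins[inside, , drop = FALSE]
    mid <- mid[inside]
    cmp_list <- lapply(seq_len(nrow(g$traversal)), function(i) {
      a <- cs$nodes[[g$traversal$child[i]]]
      b <- cs$nodes[[g$traversal$parent[i]]]
      in_a <- ivs_covers(a, mid); in_b <- ivs_covers(b, mid)
      list(child_bins = which(in_a & !in_b), parent_bins = which(in_b & !in_a),
           verdict = verdicts[i])
    })
    if (nrow(bins) > 9) next
    oracle <- tryCatch(
      bf_qtl_models(nrow(bins), cmp_list, bins[, 2] - bins[, 1] + 1),
      error = function(e) list())
    got <- tryCatch(infer_qtl_model(cs, max_qtls = nrow(bins)),
                    error = function(e) NULL)
    if (length(oracle) == 0) {
      expect_null(got)
      next
    }
    expect_false(is.null(got))
    # compare as sets of signed active-bin assignments
    norm_bins <- function(df) {
      paste(sort(paste(df$start, df$end, df$sign)), collapse = ";")
    }
    got_set <- sort(vapply(got$models, function(m) norm_bins(m$bins),
                           character(1)))
    ora_set <- sort(unique(vapply(oracle, function(a) {
      act <- which(a != 0)
      norm_bins(data.frame(start = bins[act, 1], end = bins[act, 2],
                           sign = a[act]))
    }, character(1))))
    expect_equal(got_set, ora_set)
  }
})

test_that("anchor-based refinement reproduces the printed coordinates and clips", {
  qtls <- data.frame(start = 58262383, end = 124595110, sign = "+",
                     stringsAsFactors = FALSE)
  out <- refine_qtl4(qtls, anchor_bp = 113915010, flank_mb = 10)
  expect_equal(out$start, 108915010)
  expect_equal(out$end, 118915010)
  expect_true(out$refined)

  small <- data.frame(start = 100e6, end = 130e6, sign = "+")
  out2 <- refine_qtl4(small, anchor_bp = 115e6, flank_mb = 50)
  expect_equal(c(out2$start, out2$end), c(100e6, 130e6))  # clipped: unchanged
  out3 <- refine_qtl4(small, anchor_bp = 115e6, flank_mb = 0)
  expect_equal(c(out3$start, out3$end), c(115e6, 115e6))  # point interval
  expect_error(refine_qtl4(small, anchor_bp = 10e6), "outside")
  expect_error(refine_qtl4(data.frame(start = 1e6, end = 2e6, sign = "+"),
                           anchor_bp = 1.5e6), "wider")
})

test_that("the default panel's breakpoint structure identifies all four planted QTLs", {
  g <- build_mst(default_strains())
  v <- truth_verdicts(g, default_qtls())
  cs <- manual_comparisons(default_strains(),
                           as.matrix(g$traversal[, c("child", "parent")]), v)
  m <- infer_qtl_model(cs)
  expect_equal(length(m$models), 1)
  q <- m$models[[1]]$qtls
  expect_equal(q$sign, c("+", "+", "-", "+"))
  hit <- mapply(function(s, e) any(default_qtls()$pos_bp >= s &
                                     default_qtls()$pos_bp <= e),
                q$start, q$end)
  expect_true(all(hit))
  # QTL2 and QTL3 cancellation is visible as a masked comparison
  expect_gt(length(m$models[[1]]$masked), 0)
})

test_that("removing the strains whose breakpoints isolate QTL3 collapses the model", {
  regs <- default_strains()
  regs <- regs[setdiff(names(regs), c("3.1.1.1", "4.1", "4.2"))]
  g <- build_mst(regs)
  v <- truth_verdicts(g, default_qtls())
  cs <- manual_comparisons(regs,
                           as.matrix(g$traversal[, c("child", "parent")]), v)
  m <- infer_qtl_model(cs)
  expect_lte(m$n_qtls, 3)
})

test_that("a full stochastic run recovers the four QTLs with correct signs", {
  sim <- simulate_panel(sim_config(seed = 11))
  res <- suppressMessages(sequential_analysis(sim$panel))
  q <- res$model$models[[1]]$qtls
  expect_equal(res$model$n_qtls, 4)
  expect_equal(q$sign, c("+", "+", "-", "+"))
  eff <- qtl_effect_table(res$panel, q)
  expect_equal(nrow(eff), 8)
  # direction of the per-locus genotype effect follows the inferred sign
  for (i in 1:4) {
    dH <- eff$lsmean[eff$qtl == i & eff$genotype == "H"] -
      eff$lsmean[eff$qtl == i & eff$genotype == "A"]
    expect_equal(sign(dH), if (q$sign[i] == "+") 1 else -1)
  }
})
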