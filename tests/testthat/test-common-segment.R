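test_that("narrow and broad selection enforce their group-size rules", {
  sim <- simulate_panel(sim_config(n_per_genotype = 14, partial_prob = 0,
                                   missing_rate = 0, exclusion_rate = 0,
                                   seed = 61))
  panel <- sim$panel
  panel$pheno$y <- log(panel$pheno$depot_g)
  sel <- select_strains(panel, "narrow", min_n = 12)
  expect_setequal(attr(sel, "strains"), names(default_strains()))
  expect_true(all(table(sel$strain, sel$genotype) >= 12))

  # cut one strain down to a single donor mouse: broad must drop it
  keep <- panel$pheno$strain != "4.2" |
    panel$pheno$mouse_id %in% panel$pheno$mouse_id[panel$pheno$strain == "4.2"][1]
  panel2 <- panel
  panel2$pheno <- panel2$pheno[keep, , drop = FALSE]
  panel2$geno <- panel2$geno[panel2$pheno$mouse_id, , drop = FALSE]
  sel2 <- select_strains(panel2, "broad")
  expect_false("4.2" %in% attr(sel2, "strains"))

  # empty panel -> empty selection
  empty <- panel
  empty$pheno <- empty$pheno[0, , drop = FALSE]
  empty$geno <- empty$geno[0, , drop = FALSE]
  sel3 <- select_strains(empty, "broad")
  expect_equal(nrow(sel3), 0)
})

test_that("classification detects a planted donor effect and not a null strain", {
  cfg <- sim_config(n_per_genotype = 20,
                    marker_pos_bp = c(10e6, 20e6, 30e6, 40e6),
                    strains = list(s_eff = interval_set(10e6, 20e6),
                                   s_null = interval_set(30e6, 40e6)),
                    qtls = data.frame(qtl = "Q", pos_bp = 15e6, effect = 1),
                    partial_prob = 0, missing_rate = 0, exclusion_rate = 0,
                    seed = 62)
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  panel$pheno$y <- log(panel$pheno$depot_g)
  sel <- select_strains(panel, "narrow", min_n = 12)
  cls <- classify_strains(panel, sel)
  expect_equal(cls$verdict[cls$strain == "s_eff"], "positive")
  expect_gt(cls$mean_donor[cls$strain == "s_eff"],
            cls$mean_host[cls$strain == "s_eff"])
})

test_that("literally identical genotype groups give p = 1 and a negative verdict", {
  g_host <- c("A", "A"); g_don <- c("H", "H")
  rows <- c(rep(list(g_host), 3), rep(list(g_don), 3),
            rep(list(g_host), 4), rep(list(g_don), 4))
  strain <- rep(c("s1", "s2"), c(6, 8))
  depot <- c(1, 2, 3, 1, 2, 3,                      # s1: identical groups
             1.0, 1.5, 2.0, 2.5, 1.2, 1.9, 2.4, 3.0)
  panel <- toy_panel(rows, c(10, 20), strain = strain, depot = depot,
                     bw = rep(31, 14))
  panel$pheno$y <- panel$pheno$depot_g
  sel <- select_strains(panel, "broad")
  cls <- suppressWarnings(classify_strains(panel, sel))
  expect_equal(cls$p[cls$strain == "s1"], 1)
  expect_equal(cls$verdict[cls$strain == "s1"], "negative")
})

shared_toy <- function(strain_regions, verdicts) {
  # one host + one donor mouse per strain over markers at 10, 20, 30 Mb
  pos <- c(10, 20, 30)
  rows <- list(); strain <- character()
  for (s in names(strain_regions)) {
    h <- rep("A", 3)
    d <- ifelse(ivs_covers(strain_regions[[s]], pos * 1e6), "H", "A")
    rows <- c(rows, list(h, d))
    strain <- c(strain, s, s)
  }
  panel <- toy_panel(rows, pos, strain = strain)
  cls <- data.frame(strain = names(strain_regions), verdict = verdicts,
                    stringsAsFactors = FALSE)
  shared_region_test(cls, panel)
}

test_that("shared-region predicate finds a common marker when one exists", {
  res <- shared_toy(list(P1 = interval_set(20e6, 20e6),
                         P2 = interval_set(20e6, 30e6),
                         N1 = interval_set(10e6, 10e6)),
                    c("positive", "positive", "negative"))
  expect_true(res$any_shared)
  expect_equal(res$per_marker$shared, c(FALSE, TRUE, FALSE))
})

test_that("disjoint positive donor regions share no marker", {
  res <- shared_toy(list(P1 = interval_set(10e6, 10e6),
                         P2 = interval_set(30e6, 30e6),
                         N1 = interval_set(20e6, 20e6)),
                    c("positive", "positive", "negative"))
  expect_false(res$any_shared)
  expect_false(any(res$per_marker$shared))
})

test_that("a single positive strain with a private marker is sufficient", {
  res <- shared_toy(list(P1 = interval_set(20e6, 20e6),
                         N1 = interval_set(10e6, 10e6)),
                    c("positive", "negative"))
  expect_true(res$any_shared)
  expect_true(res$per_marker$shared[2])
})

test_that("the predicate is vacuous without both verdict classes", {
  expect_warning(
    res <- shared_toy(list(P1 = interval_set(20e6, 20e6),
                           P2 = interval_set(10e6, 30e6)),
                      c("positive", "positive")),
    "vacuous")
  expect_true(res$vacuous)
  expect_false(res$any_shared)
})

test_that("classification order does not depend on strain labels", {
  cfg <- sim_config(n_per_genotype = 15,
                    marker_pos_bp = c(10e6, 20e6, 30e6, 40e6),
                    strains = list(zz = interval_set(10e6, 20e6),
                                   aa = interval_set(30e6, 40e6)),
                    qtls = data.frame(qtl = "Q", pos_bp = 15e6, effect = 1),
                    partial_prob = 0, missing_rate = 0, exclusion_rate = 0,
                    seed = 63)
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  panel$pheno$y <- log(panel$pheno$depot_g)
  sel <- select_strains(panel, "narrow", min_n = 12)
  cls <- classify_strains(panel, sel)
  # reverse the mouse order: verdicts must be identical per strain
  panel2 <- panel
  o <- rev(seq_len(nrow(panel$pheno)))
  panel2$pheno <- panel2$pheno[o, , drop = FALSE]
  panel2$geno <- panel2$geno[panel2$pheno$mouse_id, , drop = FALSE]
  sel2 <- select_strains(panel2, "narrow", min_n = 12)
  cls2 <- classify_strains(panel2, sel2)
  m <- match(cls$strain, cls2$strain)
  expect_equal(cls$verdict, cls2$verdict[m])
  expect_equal(cls$p, cls2$p[m], tolerance = 1e-10)
})
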