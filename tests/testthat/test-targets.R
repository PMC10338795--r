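test_that("CPM normalization scales each sample to one million", {
  m <- matrix(c(10, 90, 900, 5, 5, 90), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  cpm <- cpm_normalize(m)
  expect_equal(cpm[, "s1"], c(g1 = 1e4, g2 = 9e4, g3 = 9e5))
  expect_equal(unname(colSums(cpm)), rep(1e6, 2), tolerance = 1e-9)
  flat <- cpm_normalize(matrix(7, nrow = 5, ncol = 3))
  expect_true(all(flat == 1e6 / 5))
  m0 <- m; m0[, 2] <- 0
  expect_error(cpm_normalize(m0), "zero-sum")
})

test_that("the vectorized Wilcoxon engine matches stats::wilcox.test", {
  withr::with_seed(99, {
    for (i in 1:25) {
      n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
      x <- matrix(rnorm(5 * (n1 + n2)), nrow = 5)
      if (i %% 3 == 0) x[, 1] <- x[, 2] # force ties
      got <- sarcoscreen:::wilcox_rank_sum_rows(x[, 1:n1, drop = FALSE],
                                               x[, -(1:n1), drop = FALSE])
      want <- apply(x, 1, function(row) {
        suppressWarnings(stats::wilcox.test(row[1:n1], row[-(1:n1)])$p.value)
      })
      expect_equal(got, unname(want), tolerance = 1e-12)
    }
    # paired engine against the signed-rank test
    for (i in 1:15) {
      d <- matrix(rnorm(4 * 13), nrow = 4)
      got <- sarcoscreen:::wilcox_signed_rank_rows(d)
      want <- apply(d, 1, function(di) {
        suppressWarnings(stats::wilcox.test(di)$p.value)
      })
      expect_equal(got, unname(want), tolerance = 1e-12)
    }
  })
})

test_that("differential expression handles flat genes and reports CPM fields", {
  sim <- sim_expression_counts(50, de_fraction = 0, dispersion = 0.05, seed = 1)
  counts <- sim$counts
  counts["gene00001", ] <- 100 # identical in both groups after CPM? no: libsizes differ
  de <- differential_expression(counts, sim$groups)
  expect_named(de, c("gene", "log2fc", "p_value", "adj_p",
                     "mean_cpm_tumor", "mean_cpm_normal"))
  expect_true(all(de$adj_p >= de$p_value - 1e-12))
  expect_true(all(de$adj_p <= 1))

  # a gene with identical CPM values in both groups: log2fc 0, p 1
  m <- matrix(rpois(20 * 8, 50), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:8)))
  m[1, ] <- colSums(m[-1, ]) # constant CPM fraction across samples
  groups <- tibble::tibble(sample = colnames(m),
                           group = rep(c("tumor", "normal"), each = 4))
  de2 <- differential_expression(m, groups)
  expect_equal(de2$log2fc[1], 0, tolerance = 1e-9)
  expect_equal(de2$p_value[1], 1)

  expect_error(differential_expression(m, groups[c(1, 5), ]), ">= 2")
  expect_error(differential_expression(m, groups, paired = TRUE), "pair")
})

test_that("BH adjustment matches the textbook step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  # property: matches an explicit step-up implementation on random vectors
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  withr::with_seed(5, {
    for (i in 1:50) {
      p <- runif(sample(3:40, 1))
      expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
      # monotone in raw p
      expect_true(all(diff(stats::p.adjust(sort(p), "BH")) >= -1e-15))
    }
  })
})

test_that("TSG filter applies inclusive FC and strict alpha boundaries", {
  rec <- tibble::tibble(
    gene = sprintf("g%d", 1:6),
    log2fc = c(1.0, 0.99, -1.0, 2.5, 1.5, -3),
    adj_p = c(0.049, 0.001, 0.05, 0.001, 0.049, 0.0499)
  )
  out <- filter_tsg(rec)
  # g1: |log2fc| exactly 1 (inclusive) and p < 0.05 -> in
  expect_true("g1" %in% out$gene)
  # g2 fails FC, g3 fails strict alpha (p = 0.05 exactly)
  expect_false(any(c("g2", "g3") %in% out$gene))
  expect_setequal(out$gene, c("g1", "g4", "g5", "g6"))
  # brute-force oracle
  oracle <- rec$gene[abs(rec$log2fc) >= 1 & rec$adj_p < 0.05]
  expect_setequal(out$gene, oracle)
  expect_equal(out$direction[out$gene == "g6"], "down")
})

test_that("pan-cancer exclusion retains only genes with no up flags elsewhere", {
  tsgs <- sprintf("g%02d", 1:10)
  pan <- tibble::tibble(
    gene = rep(sprintf("g%02d", 1:8), each = 3),
    cancer = rep(c("BRCA", "LUAD", "COAD"), 8),
    up = FALSE
  )
  pan$up[pan$gene %in% c("g01", "g03", "g05", "g07") & pan$cancer == "BRCA"] <- TRUE
  res <- pan_cancer_exclude(tsgs, pan)
  specific <- res$gene[res$specific]
  # oracle: set difference against flagged genes
  flagged <- unique(pan$gene[pan$up])
  expect_setequal(specific, setdiff(tsgs, flagged))
  expect_length(specific, 6)
  # genes missing from the table are retained but marked unevaluated
  expect_false(res$evaluated[res$gene == "g09"])
  expect_true(res$specific[res$gene == "g09"])
})

test_that("functional classification and drug-target overlap use set semantics", {
  tsgs <- c("AKT1", "TOP2A", "DHFR", "SP7", "ALPL")
  annot <- tibble::tibble(
    gene = c("AKT1", "TOP2A", "AKT1", "SP7", "ALPL", "NOTTSG"),
    class = c("kinase", "epigenetic_factor", "transcription_factor",
              "transcription_factor", "cell_surface", "kinase")
  )
  cs <- classify_functional_sets(tsgs, annot)
  expect_equal(cs$n[cs$class == "kinase"], 1)
  # a gene annotated kinase + TF appears in both sets
  expect_true("AKT1" %in% cs$genes[[which(cs$class == "kinase")]])
  expect_true("AKT1" %in% cs$genes[[which(cs$class == "transcription_factor")]])
  expect_equal(sum(classify_functional_sets(tsgs, annot[0, ])$n), 0)

  dt <- tibble::tibble(drug = c("capivasertib", "doxorubicin", "mk2206"),
                       gene = c("AKT1", "TOP2A", "AKT1"))
  ov <- drug_target_overlap(cs, dt)
  tf_row <- which(ov$class == "transcription_factor")
  expect_equal(ov$targeted[[tf_row]], "AKT1")
  expect_equal(ov$untargeted[[tf_row]], "SP7")
  # union semantics: a gene hit by two drugs is counted once but lists both
  expect_equal(ov$n_targeted[ov$class == "kinase"], 1)
  expect_setequal(ov$gene_drugs[[which(ov$class == "kinase")]]$AKT1,
                  c("capivasertib", "mk2206"))
  none <- drug_target_overlap(cs, dt[0, ])
  expect_equal(sum(none$n_targeted), 0)
})

test_that("ACT surface filter applies inclusive FC and CPM bounds", {
  rec <- tibble::tibble(
    gene = sprintf("g%02d", 1:20),
    log2fc = c(2.0, 1.9, rep(c(2.5, 0.5), 9)),
    mean_cpm_tumor = c(90, 500, rep(c(95, 2000), 9))
  )
  surface <- sprintf("g%02d", 1:20)
  out <- act_surface_filter(surface, rec, surface)
  # g01 sits exactly on both bounds (inclusive)
  expect_true("g01" %in% out$gene)
  expect_false("g02" %in% out$gene) # log2fc 1.9 < 2
  oracle <- rec$gene[abs(rec$log2fc) >= 2 & rec$mean_cpm_tumor >= 90]
  expect_setequal(out$gene, oracle)
  expect_length(out$gene, 10)
  # candidates restricted to surface-annotated TSGs
  out2 <- act_surface_filter(c("g01", "g03"), rec, surface)
  expect_setequal(out2$gene, intersect(c("g01", "g03"), oracle))
  # missing CPM -> skipped with warning
  rec$mean_cpm_tumor[3] <- NA
  expect_warning(res <- act_surface_filter(surface, rec, surface), "skipped")
  expect_equal(attr(res, "n_skipped"), 1)
})

test_that("single-cell percent-expressed filter is strict at the boundary", {
  det <- matrix(0, nrow = 3, ncol = 6,
                dimnames = list(c("gA", "gB", "gC"),
                                paste0("type", 1:6)))
  sim <- sim_scrna_counts(det, cells_per_type = 100, seed = 1)
  counts <- sim$counts
  # hand-set expression: gA in exactly 25% of type1 (boundary), gB in 26%,
  # gC in 30% of five types
  counts[, "gA"] <- 0; counts[names(sim$clusters)[sim$clusters == "type1"][1:25], "gA"] <- 5L
  counts[, "gB"] <- 0; counts[names(sim$clusters)[sim$clusters == "type1"][1:26], "gB"] <- 5L
  counts[, "gC"] <- 0
  for (ty in paste0("type", 1:5)) {
    counts[names(sim$clusters)[sim$clusters == ty][1:30], "gC"] <- 2L
  }
  res <- scrna_percent_expressed_filter(counts, sim$clusters)
  expect_false(res$pass[res$gene == "gA"]) # exactly 25%: strict >
  expect_true(res$pass[res$gene == "gB"])
  expect_false(res$broad[res$gene == "gB"])
  expect_true(res$broad[res$gene == "gC"]) # five qualifying types
  expect_error(scrna_percent_expressed_filter(counts, sim$clusters[-1]),
               "every cell")
})

test_that("NACT overlap and multi-omic intersection are plain set operations", {
  rec <- tibble::tibble(
    gene = sprintf("g%d", 1:8),
    log2fc = c(2, 2, 2, -2, -2, -2, 0.1, 2),
    adj_p = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.9)
  )
  tsgs <- c("g1", "g2", "g4", "g5", "g7", "g9")
  ov <- nact_overlap(rec, tsgs)
  expect_equal(ov$up, c("g1", "g2"))
  expect_equal(ov$down, c("g4", "g5"))
  expect_true(all(c(ov$up, ov$down) %in% tsgs))
  none <- nact_overlap(rec, c("zz1", "zz2"))
  expect_length(none$up, 0); expect_length(none$down, 0)

  mi <- multiomic_intersect(rna_up = c("a", "b", "c"), rna_down = c("x", "y"),
                            protein_up = c("b", "c", "d"), protein_down = c("y", "z"))
  expect_equal(mi$both_up, c("b", "c"))
  expect_equal(mi$both_down, "y")
  expect_equal(mi$n_both_up, 2)
  empty <- multiomic_intersect("a", "b", "c", "d")
  expect_length(empty$both_up, 0)
})

test_that("the filter cascade is monotone: each stage is a subset of TSGs", {
  sim <- sim_expression_counts(600, de_fraction = 0.2, seed = 11)
  de <- differential_expression(sim$counts, sim$groups)
  tsg <- filter_tsg(de)
  up <- tsg$gene[tsg$direction == "up"]
  pan <- tibble::tibble(gene = up[seq_len(min(20, length(up)))],
                        cancer = "BRCA",
                        up = rep(c(TRUE, FALSE), length.out = min(20, length(up))))
  osug <- pan_cancer_exclude(up, pan)
  expect_true(all(osug$gene %in% up))
  surface <- up[seq_len(min(30, length(up)))]
  act <- act_surface_filter(up, de, surface)
  expect_true(all(act$gene %in% surface))
  expect_true(all(act$gene %in% up))
})
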