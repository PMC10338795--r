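ex_tbl <- function(starts, ends, strand = "+") {
  tibble::tibble(start = starts, end = ends, strand = strand, chrom = "chr1")
}

test_that("the classifier recognizes all five canonical event types", {
  # ES: middle exon skipped
  es <- classify_as_events(ex_tbl(c(1, 201, 401), c(100, 300, 500)),
                           ex_tbl(c(1, 401), c(100, 500)), gene = "g")
  expect_equal(es$type, "ES")
  expect_equal(c(es$start, es$end), c(201, 300))

  # A3SS on + strand: shared donor, shifted acceptor
  a3 <- classify_as_events(ex_tbl(c(1, 201), c(100, 300)),
                           ex_tbl(c(1, 181), c(100, 300)), gene = "g")
  expect_equal(a3$type, "A3SS")

  # A5SS on + strand: shifted donor, shared acceptor
  a5 <- classify_as_events(ex_tbl(c(1, 201), c(100, 300)),
                           ex_tbl(c(1, 201), c(120, 300)), gene = "g")
  expect_equal(a5$type, "A5SS")

  # IR: single exon spans the other's exon-intron-exon triplet
  ir <- classify_as_events(ex_tbl(c(1, 201), c(100, 300)),
                           ex_tbl(1, 300), gene = "g")
  expect_equal(ir$type, "IR")
  expect_equal(c(ir$start, ir$end), c(101, 200))

  # MEE: two private, non-overlapping middle exons between shared flanks
  mee <- classify_as_events(ex_tbl(c(1, 201, 501), c(100, 300, 600)),
                            ex_tbl(c(1, 351, 501), c(100, 450, 600)), gene = "g")
  expect_equal(mee$type, "MEE")
})

test_that("strand reversal swaps A3SS and A5SS and fixes the other types", {
  t1p <- ex_tbl(c(1, 201), c(100, 300), "+")
  t2p <- ex_tbl(c(1, 181), c(100, 300), "+")
  expect_equal(classify_as_events(t1p, t2p)$type, "A3SS")
  t1m <- ex_tbl(c(1, 201), c(100, 300), "-")
  t2m <- ex_tbl(c(1, 181), c(100, 300), "-")
  expect_equal(classify_as_events(t1m, t2m)$type, "A5SS")
  # ES and IR are strand-invariant
  expect_equal(classify_as_events(ex_tbl(c(1, 201, 401), c(100, 300, 500), "-"),
                                  ex_tbl(c(1, 401), c(100, 500), "-"))$type,
               "ES")
  expect_equal(classify_as_events(ex_tbl(c(1, 201), c(100, 300), "-"),
                                  ex_tbl(1, 300, "-"))$type, "IR")
})

test_that("the classifier is symmetric and translation-equivariant", {
  t1 <- ex_tbl(c(1, 201, 401), c(100, 300, 500))
  t2 <- ex_tbl(c(1, 401), c(100, 500))
  a <- classify_as_events(t1, t2, gene = "g")
  b <- classify_as_events(t2, t1, gene = "g")
  expect_equal(a$type, b$type)
  expect_equal(a$start, b$start)
  shift <- function(e, k) dplyr::mutate(e, start = start + k, end = end + k)
  sh <- classify_as_events(shift(t1, 5000), shift(t2, 5000), gene = "g")
  expect_equal(sh$start, a$start + 5000)
  expect_equal(sh$type, a$type)
})

test_that("classifier contracts: mismatched strands error, identical chains yield none", {
  expect_error(classify_as_events(ex_tbl(1, 100, "+"), ex_tbl(1, 100, "-")),
               "strand")
  none <- classify_as_events(ex_tbl(c(1, 201), c(100, 300)),
                             ex_tbl(c(1, 201), c(100, 300)))
  expect_equal(nrow(none), 0)
  # two single-exon transcripts: no introns, no events
  expect_equal(nrow(classify_as_events(ex_tbl(1, 100), ex_tbl(1, 200))), 0)
})

test_that("PSI follows the junction-normalized formula with a coverage floor", {
  expect_equal(compute_psi(30, 10), 0.75)
  expect_equal(compute_psi(40, 20, inc_junctions = 2), 0.5)
  expect_true(is.na(compute_psi(3, 2)))          # below the floor of 10
  expect_true(is.na(compute_psi(0, 0, min_total = 0)))
  expect_error(compute_psi(-1, 5), ">= 0")
  expect_error(compute_psi(5, 5, inc_junctions = 0), ">= 1")
  # scale invariance above the floor
  withr::with_seed(3, {
    inc <- rpois(50, 40); exc <- rpois(50, 30)
    keep <- inc + exc >= 10
    for (k in c(2, 7)) {
      expect_equal(compute_psi(k * inc, k * exc)[keep],
                   compute_psi(inc, exc)[keep])
    }
  })
})

test_that("PSI estimation is consistent as coverage grows", {
  tru <- sim_splicing_truths(20, psi_normal = 0.4,
                             psi_tumor = seq(0.05, 0.95, length.out = 20),
                             tumor_psi_sd = 0)
  ds <- sim_splicing_dataset(tru, n_pairs = 5, coverage_mean = 1e4, seed = 6)
  psi <- psi_table(ds$junctions)
  joined <- dplyr::inner_join(psi, ds$psi_truth, by = c("event_id", "sample_id"))
  expect_lt(mean(abs(joined$psi.x - joined$psi.y), na.rm = TRUE), 0.01)
})

test_that("differential splicing applies strict thresholds and excludes sparse events", {
  # hand-built: event A shifts by +0.3, event B exactly +0.10, event C null
  pairs <- tibble::tibble(tumor = sprintf("T%02d", 1:6),
                          normal = sprintf("N%02d", 1:6))
  psi <- dplyr::bind_rows(
    tibble::tibble(event_id = "A", sample_id = pairs$tumor, psi = 0.8 + c(-.01, .01, 0, -.005, .005, 0)),
    tibble::tibble(event_id = "A", sample_id = pairs$normal, psi = 0.5 + c(.01, -.01, 0, .005, -.005, 0)),
    tibble::tibble(event_id = "B", sample_id = pairs$tumor, psi = 0.6 + c(-.01, .01, 0, -.005, .005, 0)),
    tibble::tibble(event_id = "B", sample_id = pairs$normal, psi = 0.5 + c(-.01, .01, 0, -.005, .005, 0)),
    tibble::tibble(event_id = "C", sample_id = pairs$tumor, psi = 0.5 + c(-.02, .02, 0, -.01, .01, 0)),
    tibble::tibble(event_id = "C", sample_id = pairs$normal, psi = 0.5 + c(.02, -.02, 0, .01, -.01, 0)),
    tibble::tibble(event_id = "D", sample_id = c("T01", "N01"), psi = c(0.9, 0.1))
  )
  res <- differential_as(psi, pairs)
  expect_true(res$significant[res$event_id == "A"])
  # dPSI exactly 0.10 is NOT significant (strict >)
  expect_equal(res$dpsi[res$event_id == "B"], 0.10, tolerance = 1e-12)
  expect_false(res$significant[res$event_id == "B"])
  expect_false(res$significant[res$event_id == "C"])
  expect_false("D" %in% res$event_id) # fewer than 3 complete pairs
  excluded <- attr(res, "excluded")
  expect_equal(excluded$event_id, "D")
  # ranked by |dPSI| descending
  expect_equal(res$event_id[1], "A")
})

test_that("heterogeneity screen uses the n-1 SD and a strict 0.15 bound", {
  psi <- dplyr::bind_rows(
    tibble::tibble(event_id = "flat", sample_id = sprintf("T%d", 1:5), psi = 0.4),
    tibble::tibble(event_id = "var", sample_id = sprintf("T%d", 1:3), psi = c(0.1, 0.5, 0.9)),
    tibble::tibble(event_id = "thin", sample_id = sprintf("T%d", 1:2), psi = c(0.1, 0.9))
  )
  res <- heterogeneity_screen(psi)
  expect_equal(res$psi_sd[res$event_id == "var"], 0.4)
  expect_true(res$heterogeneous[res$event_id == "var"])
  expect_false(res$heterogeneous[res$event_id == "flat"])
  expect_false("thin" %in% res$event_id)
  expect_equal(attr(res, "excluded")$event_id, "thin")
})

test_that("planted dPSI shifts are detected and planted heterogeneity recovered", {
  # sensitivity of the differential screen at dPSI = 0.3
  det <- vapply(1:12, function(s) {
    tru <- sim_splicing_truths(30, psi_normal = 0.3, psi_tumor = 0.6,
                               tumor_psi_sd = 0.05)
    ds <- sim_splicing_dataset(tru, n_pairs = 13, coverage_mean = 100, seed = s)
    psi <- psi_table(ds$junctions)
    res <- differential_as(psi, ds$pairs)
    mean(res$significant)
  }, numeric(1))
  expect_gte(mean(det), 0.95)

  # heterogeneity recovery at planted SD 0.25
  het <- vapply(1:20, function(s) {
    tru <- sim_splicing_truths(30, psi_normal = 0.5, psi_tumor = 0.5,
                               tumor_psi_sd = 0.25)
    ds <- sim_splicing_dataset(tru, n_pairs = 13, coverage_mean = 100,
                               seed = 1000 + s)
    psi <- psi_table(ds$junctions)
    tum <- psi[psi$sample_id %in% ds$pairs$tumor, ]
    res <- heterogeneity_screen(tum)
    mean(res$heterogeneous)
  }, numeric(1))
  expect_gte(mean(het), 0.90)
})

test_that("an ES-dominant event mixture yields ES as the modal called type", {
  mix <- c(rep("ES", 13), rep("A3SS", 2), rep("A5SS", 2), rep("IR", 2), "MEE")
  tru <- sim_splicing_truths(length(mix), type = mix)
  ds <- sim_splicing_dataset(tru, seed = 9)
  called <- purrr::map_chr(split(ds$models, ds$models$gene), function(mod) {
    tx <- split(mod, mod$transcript)
    classify_as_events(tx[[1]], tx[[2]])$type[1]
  })
  tab <- table(called)
  expect_equal(names(which.max(tab)), "ES")
  expect_gt(tab[["ES"]] / sum(tab), 0.6)
})
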