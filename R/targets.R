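#' Counts-per-million normalization
#'
#' Scales every sample (column) to sum to one million.
#'
#' @param counts Genes x samples numeric matrix (or data frame coercible to
#'   one) with positive column sums.
#' @return A CPM matrix with the same dimnames.
#' @export
cpm_normalize <- function(counts) {
  m <- as.matrix(counts)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    abort(sprintf("zero-sum sample(s): %s",
                  paste(head(colnames(m)[cs <= 0], 5), collapse = ", ")))
  }
  sweep(m, 2, cs, "/") * 1e6
}

# vectorized two-sided Wilcoxon rank-sum over matrix rows; matches
# stats::wilcox.test (exact when tie-free, normal approximation with tie
# correction and continuity correction otherwise)
wilcox_rank_sum_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2); n <- n1 + n2
  X <- cbind(x1, x2)
  R <- t(apply(X, 1, rank))
  U <- rowSums(R[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  has_dup <- apply(X, 1, anyDuplicated) > 0
  tie_term <- numeric(nrow(X))
  if (any(has_dup)) {
    tie_term[has_dup] <- apply(X[has_dup, , drop = FALSE], 1, function(row) {
      tt <- tabulate(match(row, unique(row)))
      sum(tt^3 - tt)
    })
  }
  has_ties <- tie_term > 0
  p <- numeric(nrow(X))
  if (any(!has_ties)) {
    u <- U[!has_ties]
    p_exact <- ifelse(
      u > mu,
      2 * pwilcox(u - 1, n1, n2, lower.tail = FALSE),
      2 * pwilcox(u, n1, n2)
    )
    p[!has_ties] <- pmin(1, p_exact)
  }
  if (any(has_ties)) {
    u <- U[has_ties]
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term[has_ties] / (n * (n - 1)))
    z <- u - mu
    z <- z - sign(z) * 0.5 # continuity correction
    z <- ifelse(sigma2 > 0, z / sqrt(sigma2), 0)
    p[has_ties] <- pmin(1, 2 * pnorm(-abs(z)))
  }
  p
}

# vectorized two-sided Wilcoxon signed-rank on rows of paired differences
wilcox_signed_rank_rows <- function(d) {
  apply(d, 1, function(di) {
    di <- di[is.finite(di)]
    di <- di[di != 0]
    n <- length(di)
    if (n == 0) return(1)
    r <- rank(abs(di))
    V <- sum(r[di > 0])
    mu <- n * (n + 1) / 4
    ties <- anyDuplicated(abs(di)) > 0
    if (!ties && n < 50) {
      p <- if (V > mu) 2 * psignrank(V - 1, n, lower.tail = FALSE)
           else 2 * psignrank(V, n)
      return(min(1, p))
    }
    tt <- table(abs(di))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    z <- V - mu
    z <- z - sign(z) * 0.5
    z <- if (sigma2 > 0) z / sqrt(sigma2) else 0
    min(1, 2 * pnorm(-abs(z)))
  })
}

#' Differential expression by CPM, Wilcoxon and Benjamini-Hochberg
#'
#' A fully specified, engine-agnostic differential test: counts are CPM
#' normalized; the fold change is `log2((mean CPM tumor + 1)/(mean CPM
#' normal + 1))`; p-values come from a two-sided Wilcoxon rank-sum test on
#' `log2(CPM + 1)` (signed-rank on per-pair differences when `paired`), and
#' are BH-adjusted across all tested genes. Downstream filters consume only
#' (`log2fc`, `adj_p`, `mean_cpm_tumor`), which any DE engine can supply.
#'
#' @param counts Genes x samples count matrix.
#' @param groups Tibble with columns `sample`, `group` ("tumor"/"normal")
#'   and, for paired mode, `pair` (pair identifier).
#' @param paired Use the paired signed-rank test (requires `pair`).
#' @return A tibble: `gene`, `log2fc`, `p_value`, `adj_p`,
#'   `mean_cpm_tumor`, `mean_cpm_normal`.
#' @examples
#' sim <- sim_expression_counts(200, de_fraction = 0.1, seed = 1)
#' de <- differential_expression(sim$counts, sim$groups)
#' head(de)
#' @export
differential_expression <- function(counts, groups, paired = FALSE) {
  m <- as.matrix(counts)
  stopifnot(all(c("sample", "group") %in% names(groups)))
  if (!all(groups$sample %in% colnames(m))) {
    abort("every sample in `groups` must be a column of `counts`.")
  }
  tum <- groups$sample[groups$group == "tumor"]
  nor <- groups$sample[groups$group == "normal"]
  if (length(tum) < 2 || length(nor) < 2) {
    abort("need >= 2 samples per group.")
  }
  cpm <- cpm_normalize(m)
  lcpm <- log2(cpm + 1)
  mean_t <- rowMeans(cpm[, tum, drop = FALSE])
  mean_n <- rowMeans(cpm[, nor, drop = FALSE])
  log2fc <- log2((mean_t + 1) / (mean_n + 1))
  if (paired) {
    if (!"pair" %in% names(groups)) abort("paired mode requires a `pair` column.")
    gt <- groups[groups$group == "tumor", ]
    gn <- groups[groups$group == "normal", ]
    idx <- match(gt$pair, gn$pair)
    if (anyNA(idx) || length(gt$pair) != length(gn$pair)) {
      abort("unmatched pairs: every tumor sample needs exactly one normal partner.")
    }
    d <- lcpm[, gt$sample, drop = FALSE] - lcpm[, gn$sample[idx], drop = FALSE]
    p <- wilcox_signed_rank_rows(d)
  } else {
    p <- wilcox_rank_sum_rows(lcpm[, tum, drop = FALSE], lcpm[, nor, drop = FALSE])
  }
  tibble(
    gene = rownames(m) %||% sprintf("gene%05d", seq_len(nrow(m))),
    log2fc = unname(log2fc),
    p_value = unname(p),
    adj_p = p.adjust(p, method = "BH"),
    mean_cpm_tumor = unname(mean_t),
    mean_cpm_normal = unname(mean_n)
  )
}

#' Tumor-specific gene calling
#'
#' Splits a differential table into up- and down-regulated significant sets
#' with the screen's boundary conventions: the fold-change bound is inclusive
#' (|FC| >= `fc_min`, i.e. |log2fc| >= log2(fc_min)) and the adjusted-p bound
#' is strict (adj_p < `alpha`). The up set is the tumor-specific gene (TSG)
#' set.
#'
#' @param records Differential table from [differential_expression()].
#' @param fc_min Fold-change bound on the linear scale (default 2).
#' @param alpha Adjusted-p bound (default 0.05).
#' @return The input records restricted to significant genes, with a
#'   `direction` column ("up"/"down"). TSGs are `direction == "up"`.
#' @export
filter_tsg <- function(records, fc_min = 2, alpha = 0.05) {
  stopifnot(all(c("gene", "log2fc", "adj_p") %in% names(records)))
  lfc <- log2(fc_min)
  records |>
    dplyr::filter(abs(.data$log2fc) >= lfc, .data$adj_p < alpha) |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    dplyr::arrange(dplyr::desc(abs(.data$log2fc)))
}

#' Exclude genes up-regulated in other cancer types
#'
#' Keeps only tumor-specific genes with no up-regulation flag in any other
#' cancer type of a pan-cancer reference (the "specifically upregulated"
#' set). Genes absent from the reference are retained but reported as
#' unevaluated, since exclusion requires positive evidence of up-regulation
#' elsewhere.
#'
#' @param tsgs Character vector of tumor-specific genes.
#' @param pan_table Tibble `gene`, `cancer`, `up` (logical), possibly
#'   covering only part of `tsgs`.
#' @return A tibble: `gene`, `n_other_up`, `evaluated`, `specific`. The
#'   specific set is `specific == TRUE`.
#' @export
pan_cancer_exclude <- function(tsgs, pan_table) {
  stopifnot(all(c("gene", "cancer", "up") %in% names(pan_table)))
  flags <- pan_table |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_other_up = sum(.data$up), .groups = "drop")
  tibble(gene = tsgs) |>
    dplyr::left_join(flags, by = "gene") |>
    dplyr::mutate(
      evaluated = !is.na(.data$n_other_up),
      n_other_up = dplyr::coalesce(.data$n_other_up, 0L),
      specific = .data$n_other_up == 0L
    )
}

#' Intersect tumor-specific genes with functional annotation classes
#'
#' @param tsgs Character vector of tumor-specific genes.
#' @param annotation Tibble `gene`, `class` with classes among "kinase",
#'   "epigenetic_factor", "transcription_factor", "metabolism",
#'   "cell_surface"; a gene may carry several classes.
#' @return A tibble `class`, `genes` (list-column of the intersection),
#'   `n`; classes with no annotated member report n = 0.
#' @export
classify_functional_sets <- function(tsgs, annotation) {
  classes <- c("kinase", "epigenetic_factor", "transcription_factor",
               "metabolism", "cell_surface")
  if (nrow(annotation) > 0) {
    stopifnot(all(c("gene", "class") %in% names(annotation)))
    bad <- setdiff(unique(annotation$class), classes)
    if (length(bad) > 0) {
      abort(sprintf("unknown functional class(es): %s", paste(bad, collapse = ", ")))
    }
  }
  purrr::map_dfr(classes, function(cl) {
    members <- if (nrow(annotation) > 0) annotation$gene[annotation$class == cl] else character()
    hit <- sort(intersect(tsgs, members))
    tibble(class = cl, genes = list(hit), n = length(hit))
  })
}

#' Overlap functional gene classes with approved-drug targets
#'
#' @param class_sets Output of [classify_functional_sets()] (or any tibble
#'   `class`, `genes` list-column).
#' @param drug_targets Tibble `drug`, `gene` mapping drugs to target genes.
#' @return A tibble with one row per class: `class`, `targeted`,
#'   `untargeted` (list-columns), `n_targeted`, `n_untargeted`, plus a
#'   `gene_drugs` attribute-free list-column mapping each targeted gene to
#'   the drugs that hit it.
#' @export
drug_target_overlap <- function(class_sets, drug_targets) {
  stopifnot(all(c("class", "genes") %in% names(class_sets)))
  target_union <- if (nrow(drug_targets) > 0) unique(drug_targets$gene) else character()
  gene_to_drugs <- if (nrow(drug_targets) > 0) {
    split(drug_targets$drug, drug_targets$gene)
  } else list()
  class_sets |>
    dplyr::mutate(
      targeted = purrr::map(.data$genes, ~ sort(intersect(.x, target_union))),
      untargeted = purrr::map(.data$genes, ~ sort(setdiff(.x, target_union))),
      n_targeted = purrr::map_int(.data$targeted, length),
      n_untargeted = purrr::map_int(.data$untargeted, length),
      gene_drugs = purrr::map(.data$targeted,
                              ~ purrr::map(setNames(.x, .x),
                                           function(g) sort(unique(gene_to_drugs[[g]]))))
    )
}

#' Candidate cell-surface targets for adoptive cell therapy
#'
#' Within the annotated cell-surface tumor-specific genes, keeps genes with
#' |FC| >= `fc_min` (inclusive, i.e. |log2fc| >= log2(fc_min)) and mean
#' tumor CPM >= `cpm_min` (inclusive).
#'
#' @param tsgs Character vector of tumor-specific genes.
#' @param records Differential table carrying `gene`, `log2fc`,
#'   `mean_cpm_tumor`.
#' @param surface_genes Character vector of annotated cell-surface genes;
#'   candidates are restricted to `intersect(tsgs, surface_genes)`.
#' @param fc_min Linear fold-change bound (default 4).
#' @param cpm_min Mean tumor CPM bound (default 90).
#' @return A tibble of passing candidates (`gene`, `log2fc`,
#'   `mean_cpm_tumor`); genes without a CPM value are skipped, with the
#'   number skipped attached as attribute `n_skipped` (and a warning).
#' @export
act_surface_filter <- function(tsgs, records, surface_genes,
                               fc_min = 4, cpm_min = 90) {
  stopifnot(all(c("gene", "log2fc", "mean_cpm_tumor") %in% names(records)))
  candidates <- intersect(tsgs, surface_genes)
  rec <- dplyr::filter(records, .data$gene %in% candidates)
  skipped <- sum(is.na(rec$mean_cpm_tumor))
  if (skipped > 0) {
    warn(sprintf("%d candidate gene(s) skipped for missing CPM values.", skipped))
  }
  out <- rec |>
    dplyr::filter(!is.na(.data$mean_cpm_tumor),
                  abs(.data$log2fc) >= log2(fc_min),
                  .data$mean_cpm_tumor >= cpm_min) |>
    dplyr::select("gene", "log2fc", "mean_cpm_tumor") |>
    dplyr::arrange(dplyr::desc(.data$log2fc))
  attr(out, "n_skipped") <- skipped
  out
}

#' Percent-expressed filter on single-cell counts
#'
#' For each gene and cell type, the percent expressed is the fraction of that
#' type's cells with a nonzero count. A gene qualifies when its percent
#' expressed strictly exceeds `pct_min` in at least one cell type, and is
#' labelled "broad" when it qualifies in at least `broad_min` types.
#'
#' @param cell_matrix Cells x genes count matrix (cell rownames, gene
#'   colnames).
#' @param clusters Named vector cell -> cell type covering every cell.
#' @param pct_min Strict lower bound on percent expressed (default 0.25).
#' @param broad_min Minimum qualifying cell types for the broad label
#'   (default 5).
#' @return A tibble: `gene`, `qualifying_types` (list-column), `n_types`,
#'   `pass`, `broad`.
#' @export
scrna_percent_expressed_filter <- function(cell_matrix, clusters,
                                           pct_min = 0.25, broad_min = 5) {
  m <- as.matrix(cell_matrix)
  if (is.null(rownames(m)) || !all(rownames(m) %in% names(clusters))) {
    abort("every cell (row) must be present in `clusters`.")
  }
  cl <- clusters[rownames(m)]
  sizes <- table(cl)
  if (any(sizes == 0)) abort("empty cluster in `clusters`.")
  expressed <- m > 0
  pct <- rowsum(expressed + 0, group = cl)
  pct <- pct / as.vector(table(cl)[rownames(pct)]) # cell types x genes
  types <- rownames(pct)
  purrr::map_dfr(colnames(m), function(g) {
    qual <- types[pct[, g] > pct_min]
    tibble(gene = g, qualifying_types = list(qual), n_types = length(qual),
           pass = length(qual) >= 1, broad = length(qual) >= broad_min)
  })
}

#' Overlap of chemotherapy-induced expression changes with TSGs
#'
#' Intersects the significantly up/down genes of a paired post- vs
#' pre-treatment differential comparison with the tumor-specific gene set.
#'
#' @param pre_post_records Differential table (post vs pre, paired) from
#'   [differential_expression()].
#' @param tsgs Character vector of tumor-specific genes.
#' @param fc_min,alpha Significance bounds as in [filter_tsg()].
#' @return A list with `up` and `down`: sorted character vectors of TSGs
#'   up-/down-regulated after treatment.
#' @export
nact_overlap <- function(pre_post_records, tsgs, fc_min = 2, alpha = 0.05) {
  sig <- filter_tsg(pre_post_records, fc_min = fc_min, alpha = alpha)
  list(
    up = sort(intersect(sig$gene[sig$direction == "up"], tsgs)),
    down = sort(intersect(sig$gene[sig$direction == "down"], tsgs))
  )
}

#' Genes changed in the same direction at mRNA and protein level
#'
#' @param rna_up,rna_down,protein_up,protein_down Character gene sets.
#' @return A list with `both_up`, `both_down` (sorted character vectors) and
#'   `n_both_up`, `n_both_down`.
#' @export
multiomic_intersect <- function(rna_up, rna_down, protein_up, protein_down) {
  both_up <- sort(intersect(rna_up, protein_up))
  both_down <- sort(intersect(rna_down, protein_down))
  list(both_up = both_up, both_down = both_down,
       n_both_up = length(both_up), n_both_down = length(both_down))
}
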