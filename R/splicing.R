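#' Classify alternative-splicing events between two transcripts of a gene
#'
#' Compares the intron chains of two transcript models and emits the
#' classical five event types: ES (one transcript skips >= 1 internal exon
#' present in the other between shared flanking splice sites), A3SS/A5SS
#' (one boundary of a shared intron shifts; 3'/5' assigned relative to
#' strand), IR (one transcript's single exon exactly spans the other's
#' exon-intron-exon triplet) and MEE (two non-overlapping internal exons
#' between shared flanks, each private to one transcript). Intron
#' differences not matching any of the five patterns are reported as
#' "complex". Coordinates are 1-based inclusive throughout.
#'
#' @param t1,t2 Exon tables of the two transcripts: columns `start`, `end`
#'   (and optionally `gene`, `chrom`, `strand`); both must be on the same
#'   chromosome and strand.
#' @param gene,chrom,strand Used when the exon tables do not carry them.
#' @return A tibble of events: `event_id`, `gene`, `type`, `start`, `end`,
#'   `strand`, `inclusion_form`, `exclusion_form` (interval descriptions),
#'   ordered by genomic start.
#' @examples
#' t1 <- tibble::tibble(start = c(1, 201, 401), end = c(100, 300, 500))
#' t2 <- tibble::tibble(start = c(1, 401), end = c(100, 500))
#' classify_as_events(t1, t2, gene = "g1")
#' @export
classify_as_events <- function(t1, t2, gene = NULL, chrom = NULL,
                               strand = NULL) {
  meta <- function(tx, field, fallback) {
    if (field %in% names(tx)) unique(tx[[field]]) else fallback
  }
  gene <- gene %||% meta(t1, "gene", "gene")
  chrom1 <- meta(t1, "chrom", chrom %||% "chr")
  chrom2 <- meta(t2, "chrom", chrom %||% "chr")
  strand1 <- meta(t1, "strand", strand %||% "+")
  strand2 <- meta(t2, "strand", strand %||% "+")
  if (!identical(chrom1, chrom2) || !identical(strand1, strand2)) {
    abort("transcripts must share chromosome and strand.")
  }
  strand <- strand1
  as_exons <- function(tx) {
    tx[, c("start", "end")] |>
      dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
      dplyr::arrange(.data$start)
  }
  e1 <- as_exons(t1)
  e2 <- as_exons(t2)
  check_exons <- function(e) {
    if (nrow(e) == 0) abort("transcripts need >= 1 exon.")
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)])) {
      abort("exons must be non-overlapping and sorted.")
    }
  }
  check_exons(e1); check_exons(e2)
  introns <- function(e) {
    if (nrow(e) < 2) return(tibble(start = integer(), end = integer()))
    tibble(start = e$end[-nrow(e)] + 1L, end = e$start[-1] - 1L)
  }
  i1 <- introns(e1); i2 <- introns(e2)
  key <- function(x) paste(x$start, x$end)
  shared <- intersect(key(i1), key(i2))
  u1 <- i1[!key(i1) %in% shared, , drop = FALSE]
  u2 <- i2[!key(i2) %in% shared, , drop = FALSE]
  used1 <- rep(FALSE, nrow(u1)); used2 <- rep(FALSE, nrow(u2))
  events <- list()
  fmt <- function(e) paste(sprintf("%d-%d", as.integer(e$start), as.integer(e$end)),
                           collapse = ";")
  add_event <- function(type, start, end, inc, exc) {
    events[[length(events) + 1]] <<- tibble(
      gene = gene, type = type, start = start, end = end, strand = strand,
      inclusion_form = inc, exclusion_form = exc)
  }
  exons_within <- function(e, s, en) {
    dplyr::filter(e, .data$start > s, .data$end < en)
  }
  # ES / MEE: a unique intron of one transcript spanned by an intron chain of
  # the other with identical outer boundaries
  match_span <- function(ua, ub, ea, eb, used_a, used_b) {
    for (r in seq_len(nrow(ua))) {
      if (used_a[r]) next
      s <- ua$start[r]; en <- ua$end[r]
      chain <- which(ub$start >= s & ub$end <= en & !used_b)
      if (length(chain) >= 2 &&
          min(ub$start[chain]) == s && max(ub$end[chain]) == en) {
        mids <- exons_within(eb, s - 1, en + 1)
        # require the chain to be contiguous: k introns bracket k-1 exons
        if (nrow(mids) == length(chain) - 1 && nrow(mids) >= 1 &&
            nrow(exons_within(ea, s - 1, en + 1)) == 0) {
          add_event("ES", min(mids$start), max(mids$end),
                    inc = fmt(mids), exc = sprintf("%d^%d", s, en))
          used_a[r] <- TRUE; used_b[chain] <- TRUE
        }
      }
    }
    list(used_a = used_a, used_b = used_b)
  }
  res <- match_span(u1, u2, e1, e2, used1, used2)
  used1 <- res$used_a; used2 <- res$used_b
  res <- match_span(u2, u1, e2, e1, used2, used1)
  used2 <- res$used_a; used1 <- res$used_b
  # MEE: consecutive unique intron pairs sharing outer boundaries with a
  # private, non-overlapping middle exon in each transcript
  if (nrow(u1) >= 2 && nrow(u2) >= 2) {
    for (r in seq_len(nrow(u1) - 1)) {
      if (used1[r] || used1[r + 1]) next
      s <- u1$start[r]; en <- u1$end[r + 1]
      cand <- which(!used2 & u2$start == s)
      for (q in cand) {
        if (q + 1 > nrow(u2) || used2[q + 1] || u2$end[q + 1] != en) next
        ex1 <- tibble(start = u1$end[r] + 1, end = u1$start[r + 1] - 1)
        ex2 <- tibble(start = u2$end[q] + 1, end = u2$start[q + 1] - 1)
        if (ex1$end < ex2$start || ex2$end < ex1$start) {
          add_event("MEE", min(ex1$start, ex2$start), max(ex1$end, ex2$end),
                    inc = fmt(ex1), exc = fmt(ex2))
          used1[r] <- used1[r + 1] <- TRUE
          used2[q] <- used2[q + 1] <- TRUE
          break
        }
      }
    }
  }
  # IR: a unique intron of one transcript falling inside a single exon of the
  # other, with the flanking exons' outer boundaries matching that exon
  match_ir <- function(ua, ea, eb, used_a) {
    for (r in seq_len(nrow(ua))) {
      if (used_a[r]) next
      s <- ua$start[r]; en <- ua$end[r]
      left <- ea[ea$end == s - 1, , drop = FALSE]
      right <- ea[ea$start == en + 1, , drop = FALSE]
      span <- eb[eb$start %in% left$start & eb$end %in% right$end, , drop = FALSE]
      if (nrow(left) == 1 && nrow(right) == 1 && nrow(span) == 1) {
        add_event("IR", s, en,
                  inc = fmt(span), # retained-intron form
                  exc = sprintf("%d^%d", s, en))
        used_a[r] <- TRUE
      }
    }
    used_a
  }
  used1 <- match_ir(u1, e1, e2, used1)
  used2 <- match_ir(u2, e2, e1, used2)
  # A3SS / A5SS: unique introns sharing exactly one boundary
  if (any(!used1) && any(!used2)) {
    for (r in which(!used1)) {
      cand <- which(!used2 & u2$start == u1$start[r] & u2$end != u1$end[r])
      if (length(cand) > 0) {
        q <- cand[1]
        # shared donor (intron start) on +, so the acceptor side varies
        type <- if (strand == "+") "A3SS" else "A5SS"
        lo <- min(u1$end[r], u2$end[q]); hi <- max(u1$end[r], u2$end[q])
        add_event(type, lo + 1, hi,
                  inc = sprintf("%d^%d", u1$start[r], min(u1$end[r], u2$end[q])),
                  exc = sprintf("%d^%d", u1$start[r], max(u1$end[r], u2$end[q])))
        used1[r] <- TRUE; used2[q] <- TRUE
        next
      }
      cand <- which(!used2 & u2$end == u1$end[r] & u2$start != u1$start[r])
      if (length(cand) > 0) {
        q <- cand[1]
        type <- if (strand == "+") "A5SS" else "A3SS"
        lo <- min(u1$start[r], u2$start[q]); hi <- max(u1$start[r], u2$start[q])
        add_event(type, lo, hi - 1,
                  inc = sprintf("%d^%d", max(u1$start[r], u2$start[q]), u1$end[r]),
                  exc = sprintf("%d^%d", min(u1$start[r], u2$start[q]), u1$end[r]))
        used1[r] <- TRUE; used2[q] <- TRUE
      }
    }
  }
  # anything left over is a composite difference beyond the five types
  leftover <- dplyr::bind_rows(u1[!used1, , drop = FALSE], u2[!used2, , drop = FALSE])
  if (nrow(leftover) > 0) {
    for (r in seq_len(nrow(leftover))) {
      add_event("complex", leftover$start[r], leftover$end[r],
                inc = "", exc = sprintf("%d^%d", leftover$start[r], leftover$end[r]))
    }
  }
  if (length(events) == 0) {
    return(tibble(event_id = character(), gene = character(), type = character(),
                  start = integer(), end = integer(), strand = character(),
                  inclusion_form = character(), exclusion_form = character()))
  }
  dplyr::bind_rows(events) |>
    dplyr::arrange(.data$start, .data$end, .data$type) |>
    dplyr::mutate(
      event_id = sprintf("%s:%s:%d-%d", gene, .data$type,
                         as.integer(.data$start), as.integer(.data$end)),
      .before = 1)
}

#' Percent spliced in from junction counts
#'
#' Junction-count PSI with per-form junction normalization:
#' `psi = (inc/inc_junctions) / (inc/inc_junctions + exc/exc_junctions)`.
#' An ES inclusion form is supported by two junctions and its exclusion form
#' by one, so inclusion counts are halved before forming the ratio. Events
#' with total coverage below `min_total` return `NA` (too little coverage
#' for a stable estimate), as do events with zero reads on both forms.
#'
#' @param inc_count,exc_count Junction read counts (vectorized).
#' @param inc_junctions,exc_junctions Number of junctions supporting each
#'   form (>= 1).
#' @param min_total Coverage floor; below it PSI is `NA` (default 10).
#' @return PSI in \[0, 1\] or `NA`.
#' @examples
#' compute_psi(30, 10) # 0.75
#' compute_psi(40, 20, inc_junctions = 2) # 0.5
#' @export
compute_psi <- function(inc_count, exc_count, inc_junctions = 1,
                        exc_junctions = 1, min_total = 10) {
  if (any(inc_junctions < 1 | exc_junctions < 1)) {
    abort("junction counts per form must be >= 1.")
  }
  if (any(inc_count < 0 | exc_count < 0, na.rm = TRUE)) {
    abort("read counts must be >= 0.")
  }
  inc_rate <- inc_count / inc_junctions
  exc_rate <- exc_count / exc_junctions
  psi <- inc_rate / (inc_rate + exc_rate)
  psi[inc_count + exc_count < min_total] <- NA_real_
  psi[inc_rate + exc_rate == 0] <- NA_real_
  psi
}

#' PSI matrix from a junction-count table
#'
#' @param junctions Tibble `event_id`, `sample_id`, `inc_count`, `exc_count`
#'   and optionally `inc_junctions`, `exc_junctions` (default 1).
#' @param min_total Coverage floor passed to [compute_psi()].
#' @return A long tibble `event_id`, `sample_id`, `psi`.
#' @export
psi_table <- function(junctions, min_total = 10) {
  stopifnot(all(c("event_id", "sample_id", "inc_count", "exc_count")
                %in% names(junctions)))
  inc_j <- if ("inc_junctions" %in% names(junctions)) junctions$inc_junctions else 1
  exc_j <- if ("exc_junctions" %in% names(junctions)) junctions$exc_junctions else 1
  tibble(
    event_id = junctions$event_id,
    sample_id = junctions$sample_id,
    psi = compute_psi(junctions$inc_count, junctions$exc_count,
                      inc_j, exc_j, min_total = min_total)
  )
}

#' Differential splicing between paired tumor and normal samples
#'
#' Per event, the PSI difference is averaged over complete tumor/normal
#' pairs; significance comes from a two-sided paired t-test on the per-pair
#' differences, BH-adjusted across events. An event is significant when
#' |dPSI| strictly exceeds `dpsi_min` and the adjusted p is strictly below
#' `alpha`. Events with fewer than `min_pairs` complete pairs are excluded
#' and reported via the `excluded` attribute.
#'
#' @param psi Long PSI table (`event_id`, `sample_id`, `psi`) from
#'   [psi_table()].
#' @param pairs Tibble `tumor`, `normal` of paired sample ids.
#' @param dpsi_min Strict |dPSI| bound (default 0.10).
#' @param alpha Strict adjusted-p bound (default 0.01).
#' @param min_pairs Minimum complete pairs per event (default 3).
#' @return A tibble ranked by |dPSI| descending: `event_id`, `n_pairs`,
#'   `dpsi`, `p_value`, `adj_p`, `significant`; excluded events (with
#'   reasons) in `attr(, "excluded")`.
#' @export
differential_as <- function(psi, pairs, dpsi_min = 0.10, alpha = 0.01,
                            min_pairs = 3) {
  stopifnot(all(c("event_id", "sample_id", "psi") %in% names(psi)),
            all(c("tumor", "normal") %in% names(pairs)))
  wide <- psi |>
    dplyr::inner_join(
      dplyr::bind_rows(
        tibble(sample_id = pairs$tumor, role = "tumor", pair = seq_len(nrow(pairs))),
        tibble(sample_id = pairs$normal, role = "normal", pair = seq_len(nrow(pairs)))
      ),
      by = "sample_id") |>
    dplyr::select("event_id", "pair", "role", "psi") |>
    tidyr::pivot_wider(names_from = "role", values_from = "psi") |>
    dplyr::filter(!is.na(.data$tumor), !is.na(.data$normal))
  stats_tbl <- wide |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      dpsi = mean(.data$tumor - .data$normal),
      sd_d = sd(.data$tumor - .data$normal),
      .groups = "drop")
  excluded <- psi |>
    dplyr::distinct(.data$event_id) |>
    dplyr::anti_join(dplyr::filter(stats_tbl, .data$n_pairs >= min_pairs),
                     by = "event_id") |>
    dplyr::mutate(reason = sprintf("fewer than %d complete pairs", min_pairs))
  tested <- dplyr::filter(stats_tbl, .data$n_pairs >= min_pairs)
  tstat <- ifelse(tested$sd_d > 0,
                  tested$dpsi / (tested$sd_d / sqrt(tested$n_pairs)), NA)
  p <- ifelse(is.na(tstat),
              ifelse(tested$dpsi == 0, 1, 0), # zero-variance degenerate cases
              2 * pt(-abs(tstat), df = tested$n_pairs - 1))
  out <- tested |>
    dplyr::mutate(
      p_value = p,
      adj_p = p.adjust(p, method = "BH"),
      significant = abs(.data$dpsi) > dpsi_min & .data$adj_p < alpha) |>
    dplyr::select(-"sd_d") |>
    dplyr::arrange(dplyr::desc(abs(.data$dpsi)))
  attr(out, "excluded") <- excluded
  out
}

#' Screen for patient-heterogeneous splicing events
#'
#' Per event, the sample standard deviation (n-1 denominator) of tumor PSI;
#' events pass when the SD strictly exceeds `sd_min` (default 0.15, the
#' conventional threshold for calling inter-patient splicing
#' heterogeneity). Events with fewer than `min_samples` non-missing tumor
#' PSI values are excluded with a reason.
#'
#' @param psi Long PSI table restricted to tumor samples (`event_id`,
#'   `sample_id`, `psi`).
#' @param sd_min Strict SD bound (default 0.15).
#' @param min_samples Minimum non-missing tumor samples (default 3).
#' @return A tibble `event_id`, `n`, `psi_sd`, `heterogeneous`; excluded
#'   events in `attr(, "excluded")`.
#' @export
heterogeneity_screen <- function(psi, sd_min = 0.15, min_samples = 3) {
  stopifnot(all(c("event_id", "sample_id", "psi") %in% names(psi)))
  per_event <- psi |>
    dplyr::filter(!is.na(.data$psi)) |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(n = dplyr::n(), psi_sd = sd(.data$psi), .groups = "drop")
  excluded <- psi |>
    dplyr::distinct(.data$event_id) |>
    dplyr::anti_join(dplyr::filter(per_event, .data$n >= min_samples),
                     by = "event_id") |>
    dplyr::mutate(reason = sprintf("fewer than %d informative tumor samples",
                                   min_samples))
  out <- per_event |>
    dplyr::filter(.data$n >= min_samples) |>
    dplyr::mutate(heterogeneous = .data$psi_sd > sd_min) |>
    dplyr::arrange(dplyr::desc(.data$psi_sd))
  attr(out, "excluded") <- excluded
  out
}

#' Tumor-specific and patient-heterogeneous splicing events
#'
#' The combined report: events significant in the paired differential screen
#' that also pass the tumor-PSI heterogeneity screen.
#'
#' @param diff_tbl Output of [differential_as()].
#' @param het_tbl Output of [heterogeneity_screen()].
#' @return Sorted character vector of event ids.
#' @export
specific_heterogeneous_events <- function(diff_tbl, het_tbl) {
  sort(intersect(diff_tbl$event_id[diff_tbl$significant],
                 het_tbl$event_id[het_tbl$heterogeneous]))
}
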