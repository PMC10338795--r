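#' Read and write the pipeline's tabular interchange formats
#'
#' Thin readr-based wrappers around the plain-text formats the workflow
#' consumes and emits: plate CSV (well, row, col, role, drug_id, dose_uM,
#' signal), TSV count matrices (genes x samples), TSV edge lists, TSV
#' junction-count tables, and GTF transcript models (via rtracklayer).
#'
#' @param path File path.
#' @name sarcoscreen-io
NULL

#' @rdname sarcoscreen-io
#' @param plate Plate tibble from [sim_screen_plates()].
#' @export
write_plate_csv <- function(plate, path) {
  readr::write_csv(plate, path)
  invisible(path)
}

#' @rdname sarcoscreen-io
#' @export
read_plate_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    role = readr::col_character(),
                    drug_id = readr::col_character(),
                    dose_uM = readr::col_double(),
                    signal = readr::col_double(),
                    .default = readr::col_guess()))
}

#' @rdname sarcoscreen-io
#' @param counts Genes x samples matrix.
#' @export
write_count_matrix_tsv <- function(counts, path) {
  df <- as.data.frame(counts)
  df <- cbind(gene = rownames(counts), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname sarcoscreen-io
#' @export
read_count_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' @rdname sarcoscreen-io
#' @param edges Tibble `node_a`, `node_b`.
#' @export
write_edge_tsv <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}

#' @rdname sarcoscreen-io
#' @export
read_edge_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname sarcoscreen-io
#' @param junctions Junction-count tibble (see [psi_table()]).
#' @export
write_junction_tsv <- function(junctions, path) {
  readr::write_tsv(junctions, path)
  invisible(path)
}

#' @rdname sarcoscreen-io
#' @export
read_junction_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname sarcoscreen-io
#' @param models Exon tibble with columns `gene`, `transcript`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive, GTF convention).
#' @export
write_transcript_gtf <- function(models, path) {
  stopifnot(all(c("gene", "transcript", "chrom", "strand", "start", "end")
                %in% names(models)))
  lines <- sprintf(
    '%s\tsarcoscreen\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    models$chrom, as.integer(models$start), as.integer(models$end),
    models$strand, models$gene, models$transcript)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname sarcoscreen-io
#' @details `read_transcript_models()` uses rtracklayer when available and
#'   falls back to a minimal GTF exon parser otherwise; both return 1-based
#'   inclusive exon coordinates.
#' @export
read_transcript_models <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr[gr$type == "exon"])
    tibble(
      gene = as.character(df$gene_id),
      transcript = as.character(df$transcript_id),
      chrom = as.character(df$seqnames),
      strand = as.character(df$strand),
      start = df$start, end = df$end
    )
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, function(x) length(x) >= 9 && x[3] == "exon", logical(1))]
    attr_get <- function(a, key) {
      m <- regmatches(a, regexec(sprintf('%s "([^"]+)"', key), a))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    purrr::map_dfr(f, function(x) tibble(
      gene = attr_get(x[9], "gene_id"),
      transcript = attr_get(x[9], "transcript_id"),
      chrom = x[1], strand = x[7],
      start = as.integer(x[4]), end = as.integer(x[5])
    ))
  }
}
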