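#' Latent dose-response truths for a simulated drug library
#'
#' Builds the table of latent 4PL parameters behind a simulated viability
#' screen: one row per drug with its IC50, Hill slope and asymptotes. These
#' truths are what the screen generators evaluate and what recovery tests
#' compare fitted parameters against.
#'
#' @param n_drugs Number of drugs.
#' @param ic50_range Range (uM) from which log-uniform IC50s are drawn. The
#'   default spans inactive-at-screening-dose to sub-micromolar potency, so
#'   a 10 uM single-dose screen flags a realistic minority of the library.
#' @param hill_range Range of Hill slopes (uniform).
#' @param bottom_range Range of bottom asymptotes (uniform, within \[0, 1)).
#' @param seed Integer seed; the table is a pure function of it.
#' @return A tibble with columns `drug_id`, `ic50`, `hill`, `top`, `bottom`.
#' @export
sim_screen_truths <- function(n_drugs,
                              ic50_range = c(0.5, 2000),
                              hill_range = c(0.8, 2.5),
                              bottom_range = c(0, 0.2),
                              seed = 1L) {
  stopifnot(n_drugs >= 1)
  with_seed(seed, {
    tibble(
      drug_id = sprintf("drug%04d", seq_len(n_drugs)),
      ic50 = 10^runif(n_drugs, log10(ic50_range[1]), log10(ic50_range[2])),
      hill = runif(n_drugs, hill_range[1], hill_range[2]),
      top = 1,
      bottom = runif(n_drugs, bottom_range[1], bottom_range[2])
    )
  })
}

check_truths <- function(truths) {
  need <- c("drug_id", "ic50", "hill", "top", "bottom")
  if (!is.data.frame(truths) || !all(need %in% names(truths))) {
    abort("`truths` must be a data frame with columns drug_id, ic50, hill, top, bottom.")
  }
  if (nrow(truths) == 0) abort("`truths` must contain at least one drug.")
  if (any(truths$ic50 <= 0) || any(truths$hill <= 0) ||
      any(truths$top <= truths$bottom)) {
    abort("truths must satisfy ic50 > 0, hill > 0, top > bottom.")
  }
  invisible(truths)
}

#' Simulate a single-dose 384-well-style viability screen
#'
#' One drug well per truth plus a shared set of DMSO control wells, mimicking
#' a plate-reader luminescence table. Drug-well signal is the control mean
#' times the latent 4PL viability at `dose`, times multiplicative lognormal
#' noise with coefficient of variation `noise_cv` (plate readers exhibit
#' multiplicative error). Wells are laid out row-major on 16 x 24 plates.
#'
#' @param truths Truth table from [sim_screen_truths()].
#' @param dose Screening dose in uM (single concentration for every drug).
#' @param n_control_wells Number of DMSO control wells.
#' @param noise_cv Lognormal noise CV (0 = noiseless).
#' @param seed Integer seed.
#' @param base_signal Mean control-well luminescence (arbitrary units).
#' @return A tibble of wells: `well`, `plate`, `row`, `col`, `role`
#'   ("control" or "drug"), `drug_id` (NA for controls), `dose_uM`, `signal`.
#' @examples
#' plate <- sim_screen_plates(sim_screen_truths(8, seed = 1), dose = 10, seed = 2)
#' table(plate$role)
#' @export
sim_screen_plates <- function(truths, dose = 10, n_control_wells = 16,
                              noise_cv = 0.05, seed = 1L, base_signal = 1e6) {
  check_truths(truths)
  assert_scalar_number(dose, "dose")
  if (dose <= 0) abort("`dose` must be positive.")
  if (n_control_wells < 1) abort("at least one control well is required.")
  with_seed(seed, {
    n_drug <- nrow(truths)
    control_signal <- base_signal * rlnorm_cv(n_control_wells, noise_cv)
    control_mean <- mean(control_signal)
    viab <- viability_4pl(dose, truths$ic50, truths$hill, truths$top, truths$bottom)
    drug_signal <- control_mean * viab * rlnorm_cv(n_drug, noise_cv)
    n <- n_control_wells + n_drug
    idx <- seq_len(n) - 1L
    plate <- idx %/% 384L + 1L
    pos <- idx %% 384L
    row <- pos %/% 24L + 1L
    col <- pos %% 24L + 1L
    tibble(
      well = sprintf("P%02d-%s%02d", plate, LETTERS[row], col),
      plate = plate, row = row, col = col,
      role = rep(c("control", "drug"), c(n_control_wells, n_drug)),
      drug_id = c(rep(NA_character_, n_control_wells), truths$drug_id),
      dose_uM = c(rep(NA_real_, n_control_wells), rep(dose, n_drug)),
      signal = c(control_signal, drug_signal)
    )
  })
}

#' Simulate a replicated dose-response series for one drug
#'
#' Evaluates the latent 4PL at each dose and applies multiplicative lognormal
#' noise per replicate, emulating the dose-response confirmation experiments
#' that follow a primary screen.
#'
#' @param truth One-row truth (list or one-row data frame) with `ic50`,
#'   `hill`, `top`, `bottom`.
#' @param doses Distinct positive doses (uM).
#' @param replicates Replicates per dose (>= 1).
#' @param noise_cv Lognormal noise CV.
#' @param seed Integer seed.
#' @return A tibble with columns `dose`, `replicate`, `viability`.
#' @export
sim_dose_response <- function(truth, doses, replicates = 3, noise_cv = 0.05,
                              seed = 1L) {
  truth <- as.list(truth)
  if (length(doses) == 0) abort("`doses` must not be empty.")
  if (any(doses <= 0)) abort("all doses must be positive (dose = 0 is not allowed).")
  if (anyDuplicated(doses)) abort("`doses` must be distinct.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  with_seed(seed, {
    grid <- tidyr::expand_grid(dose = sort(doses), replicate = seq_len(replicates))
    mu <- viability_4pl(grid$dose, truth$ic50, truth$hill, truth$top, truth$bottom)
    dplyr::mutate(grid, viability = mu * rlnorm_cv(nrow(grid), noise_cv))
  })
}

#' Simulate a pairwise drug-combination screen
#'
#' For every unordered pair of drugs, the single-agent fractional inhibitions
#' `Pa`, `Pb` are read off the latent 4PL truths at each drug's combination
#' dose, and the observed combined inhibition is
#' `Po = clamp(Pa + Pb - Pa*Pb + bliss_excess, 0, 1)` times lognormal noise.
#' With `bliss_excess = 0` and no noise the pairs are exactly Bliss-independent.
#'
#' @param truths Truth table from [sim_screen_truths()].
#' @param doses Named numeric vector (drug_id -> dose uM) or a data frame with
#'   columns `drug_id`, `dose`; every drug needs a dose.
#' @param interactions Optional data frame `drug_a`, `drug_b`, `bliss_excess`
#'   planting interaction for specific (unordered) pairs; unlisted pairs get 0.
#' @param noise_cv Lognormal noise CV applied to `Po`.
#' @param seed Integer seed.
#' @return A tibble with one row per unordered pair: `drug_a`, `drug_b`,
#'   `dose_a`, `dose_b`, `Pa`, `Pb`, `bliss_excess`, `Po`.
#' @examples
#' tr <- sim_screen_truths(4, seed = 1)
#' doses <- setNames(tr$ic50 / 2, tr$drug_id)
#' sim_combination_screen(tr, doses, seed = 3)
#' @export
sim_combination_screen <- function(truths, doses, interactions = NULL,
                                   noise_cv = 0.02, seed = 1L) {
  check_truths(truths)
  if (is.data.frame(doses)) doses <- setNames(doses$dose, doses$drug_id)
  missing_dose <- setdiff(truths$drug_id, names(doses))
  if (length(missing_dose) > 0) {
    abort(sprintf("missing combination dose for: %s",
                  paste(head(missing_dose, 5), collapse = ", ")))
  }
  if (!is.null(interactions)) {
    unknown <- setdiff(c(interactions$drug_a, interactions$drug_b), truths$drug_id)
    if (length(unknown) > 0) {
      abort(sprintf("interaction references unknown drugs: %s",
                    paste(head(unknown, 5), collapse = ", ")))
    }
  }
  if (nrow(truths) < 2) abort("need at least two drugs for a combination screen.")
  single_p <- function(id) {
    i <- match(id, truths$drug_id)
    1 - viability_4pl(doses[id], truths$ic50[i], truths$hill[i],
                      truths$top[i], truths$bottom[i])
  }
  pair_idx <- combn(sort(truths$drug_id), 2)
  out <- tibble(
    drug_a = pair_idx[1, ], drug_b = pair_idx[2, ],
    dose_a = unname(doses[pair_idx[1, ]]), dose_b = unname(doses[pair_idx[2, ]]),
    Pa = unname(single_p(pair_idx[1, ])), Pb = unname(single_p(pair_idx[2, ])),
    bliss_excess = 0
  )
  if (!is.null(interactions)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    planted <- setNames(interactions$bliss_excess,
                        key(interactions$drug_a, interactions$drug_b))
    hit <- key(out$drug_a, out$drug_b)
    out$bliss_excess <- ifelse(hit %in% names(planted), planted[hit], 0)
  }
  with_seed(seed, {
    po <- clamp01(out$Pa + out$Pb - out$Pa * out$Pb + out$bliss_excess)
    dplyr::mutate(out, Po = po * rlnorm_cv(nrow(out), noise_cv))
  })
}

#' Single-agent anchor responses for a combination screen
#'
#' Noiseless single-agent inhibition of each drug at its combination dose,
#' the "singles" table that [synergy_matrix()] uses as Bliss anchors.
#'
#' @inheritParams sim_combination_screen
#' @return A tibble `drug_id`, `dose`, `P` (fractional inhibition).
#' @export
sim_single_agent_responses <- function(truths, doses) {
  check_truths(truths)
  if (is.data.frame(doses)) doses <- setNames(doses$dose, doses$drug_id)
  missing_dose <- setdiff(truths$drug_id, names(doses))
  if (length(missing_dose) > 0) abort("every drug needs a dose.")
  tibble(
    drug_id = truths$drug_id,
    dose = unname(doses[truths$drug_id]),
    P = 1 - viability_4pl(unname(doses[truths$drug_id]), truths$ic50,
                          truths$hill, truths$top, truths$bottom)
  )
}

#' Simulate a PPI-style network with planted hub genes
#'
#' Background nodes are wired as an Erdos-Renyi graph with the requested mean
#' degree; planted hubs form a clique and each additionally attaches to
#' `5 * background_degree` distinct random background nodes, so hubs dominate
#' every degree-driven centrality. Hub labels ("hub01", ...) sort before
#' background labels ("v0001", ...), so the deterministic ascending-label
#' tie-break of [rank_top_fraction()] never evicts a planted hub on a tie.
#'
#' @param n_nodes Total nodes (>= 3).
#' @param n_planted_hubs Number of planted hubs (< `n_nodes`).
#' @param background_degree Mean degree of the background graph.
#' @param seed Integer seed.
#' @return A list with `graph` (igraph), `edges` (tibble `node_a`, `node_b`)
#'   and `hubs` (character labels of the planted hubs).
#' @export
sim_ppi_network <- function(n_nodes, n_planted_hubs = 0, background_degree = 4,
                            seed = 1L) {
  if (n_nodes < 3) abort("`n_nodes` must be >= 3.")
  if (n_planted_hubs >= n_nodes) abort("`n_planted_hubs` must be < `n_nodes`.")
  n_bg <- n_nodes - n_planted_hubs
  hub_labels <- if (n_planted_hubs > 0) sprintf("hub%02d", seq_len(n_planted_hubs)) else character()
  bg_labels <- sprintf("v%04d", seq_len(n_bg))
  with_seed(seed, {
    p <- min(1, background_degree / max(1, n_bg - 1))
    g <- igraph::sample_gnp(n_bg, p)
    igraph::V(g)$name <- bg_labels
    if (n_planted_hubs > 0) {
      g <- igraph::add_vertices(g, n_planted_hubs, name = hub_labels)
      new_edges <- character(0)
      if (n_planted_hubs > 1) {
        cl <- combn(hub_labels, 2)
        new_edges <- c(new_edges, as.vector(cl))
      }
      k <- min(n_bg, ceiling(5 * background_degree))
      for (h in hub_labels) {
        targets <- sample(bg_labels, k)
        new_edges <- c(new_edges, rbind(h, targets))
      }
      g <- igraph::add_edges(g, new_edges)
    }
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g)
    list(
      graph = g,
      edges = tibble(node_a = el[, 1], node_b = el[, 2]),
      hubs = hub_labels
    )
  })
}

#' Simulate negative-binomial tumor/normal expression counts
#'
#' Gene-wise baseline means are lognormal; `round(de_fraction * n_genes)`
#' genes have their tumor-group mean shifted by `2^(+/- lfc_magnitude)`;
#' counts are negative binomial with the given dispersion and per-sample
#' library-size factors drawn within 2x of each other.
#'
#' @param n_genes Number of genes.
#' @param n_tumor,n_normal Samples per group (>= 2 each).
#' @param de_fraction Fraction of genes planted as differential (in \[0, 1\]).
#' @param lfc_magnitude Planted |log2 fold change|.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param seed Integer seed.
#' @param base_meanlog,base_sdlog Lognormal parameters of baseline means.
#' @return A list: `counts` (genes x samples integer matrix with dimnames),
#'   `truth` (tibble `gene`, `is_de`, `direction`), `groups` (tibble
#'   `sample`, `group`, `pair`).
#' @export
sim_expression_counts <- function(n_genes, n_tumor = 13, n_normal = 13,
                                  de_fraction = 0.1, lfc_magnitude = 2,
                                  dispersion = 0.05, seed = 1L,
                                  base_meanlog = log(150), base_sdlog = 1) {
  if (de_fraction < 0 || de_fraction > 1) abort("`de_fraction` must be in [0, 1].")
  if (n_tumor < 2 || n_normal < 2) abort("need >= 2 samples per group.")
  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    base_mu <- rlnorm(n_genes, base_meanlog, base_sdlog)
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer()
    direction <- integer(n_genes)
    direction[de_idx] <- sample(c(1L, -1L), n_de, replace = TRUE)
    fc <- 2^(direction * lfc_magnitude)
    samples <- c(sprintf("T%02d", seq_len(n_tumor)), sprintf("N%02d", seq_len(n_normal)))
    group <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
    size_factor <- runif(n_tumor + n_normal, 0.75, 1.5)
    mu <- outer(base_mu, size_factor)
    mu[, group == "tumor"] <- mu[, group == "tumor"] * fc
    counts <- if (dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow = n_genes)
    } else {
      matrix(rpois(length(mu), lambda = mu), nrow = n_genes)
    }
    dimnames(counts) <- list(genes, samples)
    pair <- c(seq_len(n_tumor), seq_len(n_normal))
    list(
      counts = counts,
      truth = tibble(gene = genes, is_de = direction != 0L, direction = direction),
      groups = tibble(sample = samples, group = group, pair = pair)
    )
  })
}

#' Latent splicing truths for a simulated PSI screen
#'
#' @param n_events Number of events.
#' @param psi_normal,psi_tumor Latent inclusion proportions (recycled).
#' @param tumor_psi_sd Between-patient SD of tumor PSI (recycled, in
#'   \[0, 0.5\]).
#' @param type AS type per event, one of "ES", "A3SS", "A5SS", "IR", "MEE"
#'   (recycled).
#' @return A tibble `event_id`, `type`, `psi_normal`, `psi_tumor`,
#'   `tumor_psi_sd`.
#' @export
sim_splicing_truths <- function(n_events, psi_normal = 0.5, psi_tumor = 0.5,
                                tumor_psi_sd = 0.05, type = "ES") {
  out <- tibble(
    event_id = sprintf("ev%04d", seq_len(n_events)),
    type = rep_len(type, n_events),
    psi_normal = rep_len(psi_normal, n_events),
    psi_tumor = rep_len(psi_tumor, n_events),
    tumor_psi_sd = rep_len(tumor_psi_sd, n_events)
  )
  if (any(out$psi_normal < 0 | out$psi_normal > 1 |
          out$psi_tumor < 0 | out$psi_tumor > 1)) {
    abort("PSI values must lie in [0, 1].")
  }
  if (any(out$tumor_psi_sd < 0 | out$tumor_psi_sd > 0.5)) {
    abort("`tumor_psi_sd` must lie in [0, 0.5].")
  }
  if (!all(out$type %in% c("ES", "A3SS", "A5SS", "IR", "MEE"))) {
    abort("unknown AS type in `type`.")
  }
  out
}

# junction multiplicities per AS type: inclusion form junctions, exclusion form
as_junction_counts <- function(type) {
  inc <- c(ES = 2L, A3SS = 1L, A5SS = 1L, IR = 1L, MEE = 2L)
  exc <- c(ES = 1L, A3SS = 1L, A5SS = 1L, IR = 1L, MEE = 2L)
  list(inc = unname(inc[type]), exc = unname(exc[type]))
}

# two-transcript exon models whose pairwise comparison yields each AS type,
# laid out on chr1 with a per-event offset; coordinates 1-based inclusive
event_gene_model <- function(event_id, type, offset) {
  ex <- function(tx, s, e) tibble(transcript = tx, start = s + offset, end = e + offset)
  exons <- switch(type,
    ES = dplyr::bind_rows(
      ex("t1", c(1, 201, 401), c(100, 300, 500)),
      ex("t2", c(1, 401), c(100, 500))
    ),
    A3SS = dplyr::bind_rows(
      ex("t1", c(1, 201), c(100, 300)),
      ex("t2", c(1, 181), c(100, 300))
    ),
    A5SS = dplyr::bind_rows(
      ex("t1", c(1, 201), c(100, 300)),
      ex("t2", c(1, 201), c(120, 300))
    ),
    IR = dplyr::bind_rows(
      ex("t1", c(1, 201), c(100, 300)),
      ex("t2", 1, 300)
    ),
    MEE = dplyr::bind_rows(
      ex("t1", c(1, 201, 501), c(100, 300, 600)),
      ex("t2", c(1, 351, 501), c(100, 450, 600))
    ),
    abort(sprintf("unknown AS type '%s'.", type))
  )
  dplyr::mutate(exons,
    gene = event_id, chrom = "chr1", strand = "+",
    transcript = paste(event_id, .data$transcript, sep = "_"),
    .before = 1
  )
}

#' Simulate a paired tumor/normal junction-count splicing dataset
#'
#' Per event and sample, a Poisson total junction coverage is split between
#' inclusion and exclusion forms by a binomial draw whose probability is the
#' per-sample PSI adjusted for the number of junctions supporting each form
#' (so the junction-normalized PSI estimator of [compute_psi()] is consistent).
#' Tumor samples draw their PSI from a normal truncated to \[0, 1\] around
#' `psi_tumor` with SD `tumor_psi_sd`; normal samples sit at `psi_normal`.
#' Each event also emits a two-transcript gene model realizing its AS type.
#'
#' @param truths Truth table from [sim_splicing_truths()].
#' @param n_pairs Number of tumor/normal pairs (>= 3).
#' @param coverage_mean Mean junction coverage per event and sample (>= 10).
#' @param seed Integer seed.
#' @return A list: `junctions` (tibble `event_id`, `sample_id`, `inc_count`,
#'   `exc_count`, `inc_junctions`, `exc_junctions`), `models` (exon tibble
#'   for all event genes), `pairs` (tibble `tumor`, `normal`), `psi_truth`
#'   (tibble of the per-sample latent PSI draws).
#' @export
sim_splicing_dataset <- function(truths, n_pairs = 13, coverage_mean = 100,
                                 seed = 1L) {
  if (n_pairs < 3) abort("`n_pairs` must be >= 3.")
  if (coverage_mean < 10) abort("`coverage_mean` must be >= 10.")
  stopifnot(all(c("event_id", "type", "psi_normal", "psi_tumor", "tumor_psi_sd")
                %in% names(truths)))
  tumor_ids <- sprintf("T%02d", seq_len(n_pairs))
  normal_ids <- sprintf("N%02d", seq_len(n_pairs))
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      event_id = truths$event_id,
      sample_id = c(tumor_ids, normal_ids)
    )
    grid <- dplyr::left_join(grid, truths, by = "event_id")
    is_tumor <- grid$sample_id %in% tumor_ids
    # truncated-normal per-tumor-sample PSI via inverse-CDF sampling
    psi <- grid$psi_normal
    mu <- grid$psi_tumor[is_tumor]
    s <- grid$tumor_psi_sd[is_tumor]
    lo <- pnorm((0 - mu) / ifelse(s > 0, s, 1))
    hi <- pnorm((1 - mu) / ifelse(s > 0, s, 1))
    u <- runif(sum(is_tumor), lo, hi)
    psi[is_tumor] <- ifelse(s > 0, mu + s * qnorm(u), mu)
    jc <- as_junction_counts(grid$type)
    total <- rpois(nrow(grid), coverage_mean)
    p_adj <- psi * jc$inc / (psi * jc$inc + (1 - psi) * jc$exc)
    p_adj[!is.finite(p_adj)] <- 0
    inc <- rbinom(nrow(grid), total, p_adj)
    junctions <- tibble(
      event_id = grid$event_id, sample_id = grid$sample_id,
      inc_count = inc, exc_count = total - inc,
      inc_junctions = jc$inc, exc_junctions = jc$exc
    )
    models <- purrr::map2_dfr(
      truths$event_id, seq_len(nrow(truths)) - 1L,
      function(id, i) event_gene_model(id, truths$type[i + 1L], i * 10000L)
    )
    list(
      junctions = junctions,
      models = models,
      pairs = tibble(tumor = tumor_ids, normal = normal_ids),
      psi_truth = tibble(event_id = grid$event_id, sample_id = grid$sample_id,
                         psi = psi)
    )
  })
}

#' Simulate a cells-by-genes single-cell count matrix with cell types
#'
#' Minimal single-cell fixture for the percent-expressed filter: each gene is
#' assigned a per-cell-type detection probability and counts are Bernoulli x
#' Poisson, so the fraction of expressing cells per type is controlled.
#'
#' @param detection Matrix or data frame of detection probabilities,
#'   genes x cell types (dimnames used as labels).
#' @param cells_per_type Cells per cell type.
#' @param mean_count Mean nonzero count.
#' @param seed Integer seed.
#' @return A list: `counts` (cells x genes matrix), `clusters` (named
#'   character vector cell -> cell type).
#' @export
sim_scrna_counts <- function(detection, cells_per_type = 50, mean_count = 3,
                             seed = 1L) {
  detection <- as.matrix(detection)
  if (is.null(rownames(detection)) || is.null(colnames(detection))) {
    abort("`detection` needs gene rownames and cell-type colnames.")
  }
  with_seed(seed, {
    types <- colnames(detection)
    cells <- sprintf("%s_c%03d", rep(types, each = cells_per_type),
                     rep(seq_len(cells_per_type), length(types)))
    clusters <- setNames(rep(types, each = cells_per_type), cells)
    counts <- matrix(0L, nrow = length(cells), ncol = nrow(detection),
                     dimnames = list(cells, rownames(detection)))
    for (ty in types) {
      rows <- which(clusters == ty)
      for (g in rownames(detection)) {
        on <- runif(length(rows)) < detection[g, ty]
        counts[rows[on], g] <- rpois(sum(on), mean_count) + 1L
      }
    }
    list(counts = counts, clusters = clusters)
  })
}
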