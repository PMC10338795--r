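#' Bliss-expected combined response of two independent drugs
#'
#' Under Bliss independence two drugs act like independent probabilistic
#' events, so the expected combined fractional inhibition is
#' `Pt = Pa + Pb - Pa*Pb`, equivalently `1 - (1-Pa)(1-Pb)`.
#'
#' @param pa,pb Fractional single-agent inhibitions in \[0, 1\] (vectorized).
#' @return The Bliss-expected combined inhibition `Pt`.
#' @examples
#' bliss_expected(0.5, 0.5) # 0.75
#' @export
bliss_expected <- function(pa, pb) {
  if (any(pa < 0 | pa > 1 | pb < 0 | pb > 1, na.rm = TRUE)) {
    abort("fractional responses must lie in [0, 1].")
  }
  pa + pb - pa * pb
}

#' Bliss Independence index
#'
#' Ratio of the observed combined response to the Bliss-expected one,
#' `BI = Po / Pt`. Values above 1 indicate more inhibition than independent
#' action predicts.
#'
#' @param po Observed combined fractional inhibition.
#' @param pt Bliss-expected inhibition from [bliss_expected()]; must be > 0
#'   (two inert single agents leave the index undefined).
#' @return The Bliss index (vectorized).
#' @export
bliss_index <- function(po, pt) {
  if (any(pt <= 0, na.rm = TRUE)) {
    abort("Bliss index is undefined when the expected response Pt is <= 0 (both single agents inert).")
  }
  po / pt
}

#' Classify a drug-drug interaction from its Bliss index
#'
#' BI < 1 is antagonistic, BI = 1 additive, BI > 1 synergistic (within a
#' floating-point tolerance around 1), and "obvious" synergy requires BI
#' strictly above `obvious_threshold` (default 1.3).
#'
#' @param bi Bliss index (vectorized, finite).
#' @param obvious_threshold Strict threshold for obvious synergy.
#' @param additive_tol Tolerance around BI = 1 inside which the interaction
#'   is called additive.
#' @return A tibble: `BI`, `label` ("antagonistic"/"additive"/"synergistic"),
#'   `obvious_synergy`.
#' @examples
#' classify_interaction(c(0.5, 1, 1.31))
#' @export
classify_interaction <- function(bi, obvious_threshold = 1.3,
                                 additive_tol = 1e-9) {
  if (any(!is.finite(bi))) abort("`bi` must be finite.")
  label <- dplyr::case_when(
    abs(bi - 1) <= additive_tol ~ "additive",
    bi < 1 ~ "antagonistic",
    TRUE ~ "synergistic"
  )
  tibble(BI = bi, label = label, obvious_synergy = bi > obvious_threshold)
}

#' Chou-Talalay combination index
#'
#' `CI = DA/da + DB/db`, where `da`/`db` are the single-agent IC50 doses and
#' `DA`/`DB` the doses of each drug in the combination that reach the IC50
#' effect. CI < 1 indicates synergy, CI = 1 additivity, CI > 1 antagonism.
#'
#' @param DA,DB Combination doses reaching the IC50 effect (>= 0; one may
#'   be 0).
#' @param da,db Single-agent IC50 doses (> 0).
#' @return The combination index (vectorized).
#' @examples
#' chou_talalay_ci(1, 0, 1, 2) # 1: drug A alone at its own IC50
#' chou_talalay_ci(0.5, 1, 2, 4) # 0.5: synergy
#' @export
chou_talalay_ci <- function(DA, DB, da, db) {
  if (any(da <= 0 | db <= 0)) abort("single-agent IC50 doses must be positive.")
  if (any(DA < 0 | DB < 0)) abort("combination doses must be >= 0.")
  DA / da + DB / db
}

#' Label a Chou-Talalay combination index
#'
#' @param ci Combination index from [chou_talalay_ci()].
#' @param additive_tol Tolerance around CI = 1.
#' @return Character vector of labels.
#' @export
classify_ci <- function(ci, additive_tol = 1e-9) {
  dplyr::case_when(
    abs(ci - 1) <= additive_tol ~ "additive",
    ci < 1 ~ "synergistic",
    TRUE ~ "antagonistic"
  )
}

#' Combination doses reaching the IC50 effect along a fixed-ratio series
#'
#' Log-linear interpolation of a fixed-ratio combination dose-response to the
#' 50%-inhibition level, yielding the `DA`/`DB` inputs of
#' [chou_talalay_ci()]. Doses of drug A and B are assumed proportional along
#' the series.
#'
#' @param dose_a,dose_b Doses of each drug along the series (same length).
#' @param inhibition Observed combined fractional inhibition at each point.
#' @param effect Effect level to interpolate to (default 0.5).
#' @return A list with `DA` and `DB`.
#' @export
interpolate_ic50_doses <- function(dose_a, dose_b, inhibition, effect = 0.5) {
  stopifnot(length(dose_a) == length(dose_b),
            length(dose_a) == length(inhibition))
  ord <- order(dose_a + dose_b)
  dose_a <- dose_a[ord]; dose_b <- dose_b[ord]; inhibition <- inhibition[ord]
  above <- which(inhibition >= effect)
  if (length(above) == 0) {
    abort("the combination never reaches the requested effect level.")
  }
  j <- above[1]
  if (j == 1 || inhibition[j] == effect) {
    return(list(DA = dose_a[j], DB = dose_b[j]))
  }
  i <- j - 1
  # interpolate in log-total-dose against inhibition
  lt <- log(dose_a + dose_b)
  f <- (effect - inhibition[i]) / (inhibition[j] - inhibition[i])
  total <- exp(lt[i] + f * (lt[j] - lt[i]))
  frac_a <- dose_a[j] / (dose_a[j] + dose_b[j])
  list(DA = total * frac_a, DB = total * (1 - frac_a))
}

#' Score a pairwise combination screen with the Bliss model
#'
#' Joins each observed pair response to its two single-agent anchors (matched
#' on drug and dose), computes `Pt`, `BI` and the interaction label per pair,
#' and summarizes how many pairs show obvious synergy (BI strictly above the
#' threshold). Replicated pair rows are averaged before scoring; per-replicate
#' indices are kept for dispersion.
#'
#' @param pairs Tibble of combination responses: `drug_a`, `drug_b`,
#'   `dose_a`, `dose_b`, `Po` (one or more rows per pair).
#' @param singles Tibble of single-agent anchors: `drug_id`, `dose`, `P`.
#' @param obvious_threshold Strict BI threshold for obvious synergy.
#' @return A `synergy_matrix` object: list with `table` (long per-pair
#'   tibble), `matrix` (upper-triangle BI matrix over the drug set),
#'   `replicates` (per-replicate BI tibble) and `summary` (tibble `n_pairs`,
#'   `n_obvious`, `fraction_obvious` as a 1-decimal percentage).
#' @examples
#' tr <- sim_screen_truths(6, seed = 1)
#' doses <- setNames(tr$ic50, tr$drug_id)
#' combos <- sim_combination_screen(tr, doses, noise_cv = 0, seed = 2)
#' sm <- synergy_matrix(combos, sim_single_agent_responses(tr, doses))
#' sm$summary
#' @export
synergy_matrix <- function(pairs, singles, obvious_threshold = 1.3) {
  stopifnot(all(c("drug_a", "drug_b", "dose_a", "dose_b", "Po") %in% names(pairs)))
  stopifnot(all(c("drug_id", "dose", "P") %in% names(singles)))
  anchors <- dplyr::distinct(singles, .data$drug_id, .data$dose, .data$P)
  # drop any precomputed response columns so the anchors are authoritative
  pairs <- pairs[, setdiff(names(pairs), c("Pa", "Pb", "Pt", "BI")), drop = FALSE]
  scored <- pairs |>
    dplyr::left_join(anchors, by = c(drug_a = "drug_id", dose_a = "dose")) |>
    dplyr::rename(Pa = "P") |>
    dplyr::left_join(anchors, by = c(drug_b = "drug_id", dose_b = "dose")) |>
    dplyr::rename(Pb = "P")
  if (anyNA(scored$Pa) || anyNA(scored$Pb)) {
    bad <- scored[is.na(scored$Pa) | is.na(scored$Pb), ]
    abort(sprintf("missing single-agent anchor at the combination dose for %d pair(s), e.g. %s + %s.",
                  nrow(bad), bad$drug_a[1], bad$drug_b[1]))
  }
  per_rep <- scored |>
    dplyr::mutate(Pt = bliss_expected(.data$Pa, .data$Pb),
                  BI = bliss_index(.data$Po, .data$Pt))
  tab <- per_rep |>
    dplyr::group_by(.data$drug_a, .data$drug_b, .data$dose_a, .data$dose_b,
                    .data$Pa, .data$Pb, .data$Pt) |>
    dplyr::summarise(Po = mean(.data$Po), n_replicates = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(BI = bliss_index(.data$Po, .data$Pt))
  cls <- classify_interaction(tab$BI, obvious_threshold = obvious_threshold)
  tab$label <- cls$label
  tab$obvious_synergy <- cls$obvious_synergy
  tab <- dplyr::arrange(tab, .data$drug_a, .data$drug_b)
  drugs <- sort(unique(c(tab$drug_a, tab$drug_b)))
  m <- matrix(NA_real_, length(drugs), length(drugs),
              dimnames = list(drugs, drugs))
  ia <- match(tab$drug_a, drugs); ib <- match(tab$drug_b, drugs)
  m[cbind(pmin(ia, ib), pmax(ia, ib))] <- tab$BI
  summary <- tibble(
    n_pairs = nrow(tab),
    n_obvious = sum(tab$obvious_synergy),
    fraction_obvious = percent_of(sum(tab$obvious_synergy), nrow(tab), 1)
  )
  structure(
    list(table = tab, matrix = m,
         replicates = dplyr::select(per_rep, "drug_a", "drug_b", "Po", "Pt", "BI"),
         summary = summary, obvious_threshold = obvious_threshold),
    class = "synergy_matrix")
}

#' @export
print.synergy_matrix <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Bliss synergy matrix: %d pairs, %d obvious synergies (BI > %.2g): %.1f%%\n",
              s$n_pairs, s$n_obvious, x$obvious_threshold, s$fraction_obvious))
  invisible(x)
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' `volume = pi/6 * length * width * height`, in cubic millimetres when the
#' dimensions are in millimetres.
#'
#' @param length,width,height Positive dimensions (mm), vectorized.
#' @return Tumor volume (mm^3).
#' @examples
#' tumor_volume(6, 5, 4) # 20 * pi
#' @export
tumor_volume <- function(length, width, height) {
  if (any(length <= 0 | width <= 0 | height <= 0)) {
    abort("all tumor dimensions must be positive.")
  }
  pi / 6 * length * width * height
}
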