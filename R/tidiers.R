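#' Tidy a 4PL dose-response fit
#'
#' @param x A `dr_fit` from [fit_dose_response()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.dr_fit <- function(x, ...) {
  tibble(term = c("top", "bottom", "ic50", "hill"),
         estimate = c(x$top, x$bottom, x$ic50, x$hill))
}

#' One-row summary of a 4PL dose-response fit
#'
#' @inheritParams tidy.dr_fit
#' @return A one-row tibble: `ic50`, `hill`, `top`, `bottom`, `sse`,
#'   `converged`, `n`.
#' @exportS3Method generics::glance
glance.dr_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, top = x$top, bottom = x$bottom,
         sse = x$sse, converged = x$converged, n = x$n)
}

#' Long-form pair table of a synergy matrix
#'
#' @param x A `synergy_matrix` from [synergy_matrix()].
#' @param ... Unused.
#' @return The per-pair tibble (`drug_a`, `drug_b`, doses, `Pa`, `Pb`,
#'   `Po`, `Pt`, `BI`, `label`, `obvious_synergy`).
#' @exportS3Method generics::tidy
tidy.synergy_matrix <- function(x, ...) x$table

#' One-row summary of a synergy matrix
#'
#' @inheritParams tidy.synergy_matrix
#' @return A one-row tibble: `n_pairs`, `n_obvious`, `fraction_obvious`
#'   (percentage, 1 decimal).
#' @exportS3Method generics::glance
glance.synergy_matrix <- function(x, ...) x$summary

#' Per-method membership table of a hub consensus
#'
#' @param x A `hub_consensus` from [consensus_hubs()].
#' @param ... Unused.
#' @return A tibble `method`, `node`, `in_consensus`, one row per node in a
#'   method's top set.
#' @exportS3Method generics::tidy
tidy.hub_consensus <- function(x, ...) {
  purrr::imap_dfr(x$top_sets, function(nodes, method) {
    tibble(method = method, node = nodes,
           in_consensus = nodes %in% x$consensus)
  })
}

#' One-row summary of a hub consensus
#'
#' @inheritParams tidy.hub_consensus
#' @return A one-row tibble: `n_nodes`, `fraction`, `top_set_size`,
#'   `n_consensus`.
#' @exportS3Method generics::glance
glance.hub_consensus <- function(x, ...) {
  tibble(n_nodes = nrow(x$scores), fraction = x$fraction,
         top_set_size = length(x$top_sets[[1]]),
         n_consensus = length(x$consensus))
}
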