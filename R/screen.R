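#' Normalize a plate of raw luminescence signals to relative viability
#'
#' Relative viability of each drug well is its signal divided by the
#' aggregated DMSO control signal of the same plate set. Viabilities above 1
#' (apparent stimulation) are retained rather than clipped, so they stay
#' visible for QC.
#'
#' @param plate A plate tibble as produced by [sim_screen_plates()] or
#'   [read_plate_csv()]: columns `role` ("drug"/"control"), `drug_id`,
#'   `dose_uM`, `signal`.
#' @param cell_line Label attached to every record.
#' @param aggregate How to aggregate control wells: "mean" (default,
#'   linear-unbiased) or "median".
#' @return A tibble of viability records: `drug_id`, `cell_line`, `dose_uM`,
#'   `viability`, `inhibition` (= 1 - viability exactly).
#' @examples
#' plate <- sim_screen_plates(sim_screen_truths(5, seed = 1), dose = 10,
#'                            noise_cv = 0, seed = 2)
#' normalize_plate(plate, "143B")
#' @export
normalize_plate <- function(plate, cell_line, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("role", "drug_id", "dose_uM", "signal") %in% names(plate)))
  controls <- plate$signal[plate$role == "control"]
  if (length(controls) == 0) abort("plate has no control wells.")
  ref <- if (aggregate == "mean") mean(controls) else stats::median(controls)
  if (!is.finite(ref) || ref <= 0) {
    abort("control signal aggregate must be positive.")
  }
  drugs <- dplyr::filter(plate, .data$role == "drug")
  tibble(
    drug_id = drugs$drug_id,
    cell_line = cell_line,
    dose_uM = drugs$dose_uM,
    viability = drugs$signal / ref,
    inhibition = 1 - drugs$signal / ref
  )
}

#' Call screening hits across cell lines
#'
#' A drug is a hit when its fractional inhibition strictly exceeds the
#' threshold in at least one cell line (the ">60% in at least one line" rule
#' of a primary screen). Output is one row per drug with per-line inhibition
#' spread into columns, sorted by maximum inhibition descending, ties broken
#' by drug label.
#'
#' @param records Viability records from [normalize_plate()], potentially
#'   covering several cell lines; one record per (drug, line, dose).
#' @param inhibition_threshold Strict inhibition threshold (default 0.60).
#' @return A tibble: `drug_id`, one `inhibition_<line>` column per cell line,
#'   `max_inhibition`, `hit`.
#' @export
call_hits <- function(records, inhibition_threshold = 0.60) {
  stopifnot(all(c("drug_id", "cell_line", "inhibition") %in% names(records)))
  dup <- records |>
    dplyr::distinct(.data$drug_id, .data$cell_line,
                    dose = if ("dose_uM" %in% names(records)) .data$dose_uM else NA,
                    .data$inhibition) |>
    dplyr::count(.data$drug_id, .data$cell_line, .data$dose) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("conflicting duplicate records for %d (drug, line, dose) combinations, e.g. %s / %s",
                  nrow(dup), dup$drug_id[1], dup$cell_line[1]))
  }
  wide <- records |>
    dplyr::distinct(.data$drug_id, .data$cell_line, .data$inhibition) |>
    tidyr::pivot_wider(names_from = "cell_line", values_from = "inhibition",
                       names_prefix = "inhibition_")
  inh_cols <- grep("^inhibition_", names(wide), value = TRUE)
  wide |>
    dplyr::mutate(
      max_inhibition = do.call(pmax, c(dplyr::across(dplyr::all_of(inh_cols)),
                                       na.rm = TRUE)),
      hit = purrr::pmap_lgl(dplyr::across(dplyr::all_of(inh_cols)),
                            function(...) any(c(...) > inhibition_threshold,
                                              na.rm = TRUE))
    ) |>
    dplyr::arrange(dplyr::desc(.data$max_inhibition), .data$drug_id)
}

sse_4pl <- function(par, log_dose, viab) {
  pred <- par[2] + (par[1] - par[2]) / (1 + 10^((log_dose - par[3]) * par[4]))
  sum((viab - pred)^2)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit
#' `v(d) = bottom + (top - bottom) / (1 + (d/ic50)^hill)` in log-dose
#' parameterization with multi-start bounded optimization (5 heuristic
#' starts, L-BFGS-B; top/bottom bounded to \[-0.1, 1.5\]). The reported IC50
#' is the fitted midpoint parameter.
#'
#' @param doses Positive doses (uM), at least 4 distinct values.
#' @param viabilities Fractional viabilities, same length as `doses`.
#' @return A `dr_fit` object (also a list) with elements `top`, `bottom`,
#'   `ic50`, `hill`, `sse`, `converged`, `n`, and the data used. Access
#'   tidied parameters with [tidy()] / [glance()].
#' @examples
#' d <- 10^seq(-2, 2, length.out = 8)
#' fit <- fit_dose_response(d, viability_4pl(d, ic50 = 1, hill = 1))
#' glance(fit)
#' @export
fit_dose_response <- function(doses, viabilities) {
  if (length(doses) != length(viabilities)) {
    abort("`doses` and `viabilities` must have the same length.")
  }
  keep <- is.finite(doses) & is.finite(viabilities)
  doses <- doses[keep]; viabilities <- viabilities[keep]
  if (any(doses <= 0)) abort("doses must be positive.")
  if (length(unique(doses)) < 4) abort("need >= 4 distinct doses for a 4PL fit.")
  new_fit <- function(top, bottom, ic50, hill, sse, converged) {
    structure(
      list(top = top, bottom = bottom, ic50 = ic50, hill = hill,
           sse = sse, converged = converged, n = length(doses),
           data = tibble(dose = doses, viability = viabilities)),
      class = "dr_fit")
  }
  if (sd(viabilities) == 0) {
    return(new_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                   sse = 0, converged = FALSE))
  }
  ld <- log10(doses)
  # starts: asymptotes from viability quantiles, midpoint from dose quantiles
  q <- stats::quantile(ld, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- list(
    c(max(viabilities), min(viabilities), q[2], 1),
    c(max(viabilities), min(viabilities), q[1], 1),
    c(max(viabilities), min(viabilities), q[3], 1),
    c(1, 0, mean(ld), 2),
    c(1, 0, q[2], 0.5)
  )
  lower <- c(-0.1, -0.1, min(ld) - 3, 0.05)
  upper <- c(1.5, 1.5, max(ld) + 3, 20)
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    res <- tryCatch(
      optim(st, sse_4pl, log_dose = ld, viab = viabilities,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    return(new_fit(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, FALSE))
  }
  p <- best$par
  # orient so hill > 0 describes a decreasing curve with top >= bottom
  top <- max(p[1], p[2]); bottom <- min(p[1], p[2])
  if (p[1] < p[2]) p[4] <- -p[4]
  new_fit(top, bottom, 10^p[3], abs(p[4]), best$value,
          converged = best$convergence == 0 && top > bottom)
}

#' Predict viability from a fitted dose-response curve
#'
#' @param object A `dr_fit` from [fit_dose_response()].
#' @param newdata Doses (uM) to predict at.
#' @param ... Unused.
#' @return Predicted fractional viabilities.
#' @export
predict.dr_fit <- function(object, newdata, ...) {
  if (!isTRUE(object$converged)) abort("cannot predict from a non-converged fit.")
  viability_4pl(newdata, object$ic50, object$hill, object$top, object$bottom)
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("4PL dose-response fit (", x$n, " points)\n", sep = "")
  if (isTRUE(x$converged)) {
    cat(sprintf("  ic50 = %.4g uM, hill = %.3g, top = %.3g, bottom = %.3g, sse = %.3g\n",
                x$ic50, x$hill, x$top, x$bottom, x$sse))
  } else {
    cat("  not converged\n")
  }
  invisible(x)
}

#' Choose a sub-IC50 dose for a combination screen
#'
#' Returns the largest dose on a candidate grid whose predicted inhibition is
#' strictly below `max_inhibition` (the "inhibition of less than 50%" rule
#' for picking combination doses from dose-response relationships).
#'
#' @param fit A converged `dr_fit`.
#' @param max_inhibition Strict upper bound on predicted inhibition
#'   (default 0.5).
#' @param grid Candidate doses; default half-log steps spanning three decades
#'   either side of the fitted IC50.
#' @return A single dose (uM).
#' @export
select_combination_dose <- function(fit, max_inhibition = 0.5, grid = NULL) {
  if (!inherits(fit, "dr_fit") || !isTRUE(fit$converged)) {
    abort("`fit` must be a converged dr_fit.")
  }
  if (is.null(grid)) {
    grid <- 10^seq(log10(fit$ic50) - 3, log10(fit$ic50) + 3, by = 0.5)
  }
  grid <- sort(grid)
  inhibition <- 1 - predict(fit, grid)
  ok <- inhibition < max_inhibition
  if (!any(ok)) {
    abort(sprintf(
      "no grid dose keeps predicted inhibition below %.2f (minimum achieved: %.3f at %.4g uM).",
      max_inhibition, min(inhibition), grid[which.min(inhibition)]))
  }
  max(grid[ok])
}
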