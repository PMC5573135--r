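# The within-category (density) observer model: one Gaussian density per
# response category, estimated by maximum likelihood (sample moments) from
# the trials that reveal which category the participant had in mind.

#' Fit the per-category Gaussian densities of the within-category model
#'
#' Estimates, for each requested category, the Gaussian density implied by
#' the participant's responses in the fit window, using the sample moments
#' (the maximum-likelihood estimators). In `"RB"` mode only the second
#' stimulus dimension is modeled (mean and variance per category: 8 free
#' parameters over A-D); in `"II"` mode the full bivariate mean and
#' covariance are fitted per category. Trial selection follows
#' [select_fitting_trials()]. Fitted variances (and covariance diagonals)
#' are floored at `var_floor`; a non-positive-definite fitted covariance is
#' ridged minimally until invertible.
#'
#' @param session A `catrep_session` with responses.
#' @param trial_window Integer trial indices to fit on (default 301:500,
#'   the last 200 training trials).
#' @param categories Category labels to fit (default A-D).
#' @param mode `"RB"` (dim2 only) or `"II"` (bivariate); defaults to the
#'   session's structure kind.
#' @param var_floor Lower bound on fitted variances, in squared stimulus
#'   units.
#' @return An object of class `density_params`: per-category estimates plus
#'   `alpha = NA` (the decision noise is fitted separately, conditional on
#'   these estimates).
#' @seealso [density_region_prob()], [fit_alpha()]
#' @export
fit_density_params <- function(session, trial_window = 301:500,
                               categories = cat_labels,
                               mode = session$structure_kind,
                               var_floor = 1e-4) {
  stopifnot(mode %in% c("RB", "II"), length(trial_window) >= 1L)
  window <- session$trials[session$trials$trial %in% trial_window, ,
                           drop = FALSE]
  ests <- list()
  missing_labels <- character(0)
  for (lab in categories) {
    sel <- select_fitting_trials(session, "density", lab, trials = window)
    if (nrow(sel) < 3L) {
      missing_labels <- c(missing_labels, lab)
      next
    }
    if (mode == "RB") {
      v <- max(stats::var(sel$dim2), var_floor)
      ests[[lab]] <- list(n = nrow(sel), mean = mean(sel$dim2), var = v)
    } else {
      x <- cbind(sel$dim1, sel$dim2)
      cv <- stats::cov(x)
      diag(cv) <- pmax(diag(cv), var_floor)
      while (inherits(tryCatch(chol(cv), error = identity), "error")) {
        cv <- cv + diag(var_floor, 2)
      }
      ests[[lab]] <- list(n = nrow(sel), mean = colMeans(x), cov = cv)
    }
  }
  if (length(missing_labels) > 0L) {
    stop(errorCondition(
      paste0("underdetermined categories (fewer than 3 usable trials): ",
             paste(missing_labels, collapse = ", ")),
      labels = missing_labels,
      class = c("catrep_underdetermined_category", "error", "condition")
    ))
  }
  structure(list(mode = mode, categories = ests, alpha = NA_real_,
                 fitted_categories = names(ests), var_floor = var_floor),
            class = "density_params")
}

# Gaussian density of stimuli (n x 2 matrix) under one category estimate.
density_value <- function(params, est, stimulus) {
  stimulus <- unname(rbind(stimulus))
  if (params$mode == "RB") {
    stats::dnorm(stimulus[, 2], mean = est$mean, sd = sqrt(est$var))
  } else {
    si <- solve(est$cov)
    centered <- sweep(stimulus, 2, est$mean)
    q <- rowSums((centered %*% si) * centered)
    exp(-q / 2) / (2 * pi * sqrt(det(est$cov)))
  }
}

#' Region probability under the within-category model
#'
#' The probability of locating a stimulus in the perceptual region of
#' category X rather than the contrasting category Y is the density ratio
#' `f_X(d) / (f_X(d) + f_Y(d))`. The same rule applies at training and at
#' test, which is why the density model can transfer to the untrained B-C
#' contrast. If both densities underflow to zero the convention is maximum
#' ignorance, 0.5.
#'
#' @param params A `density_params` object.
#' @param stimulus Numeric 2-vector or n x 2 matrix of `(dim1, dim2)`.
#' @param pair Length-2 label vector `(X, Y)`; the returned probability is
#'   for the first element.
#' @return `p(C_X | d)` in `[0, 1]`, vectorized over stimulus rows.
#' @export
density_region_prob <- function(params, stimulus, pair) {
  stopifnot(inherits(params, "density_params"), length(pair) == 2L)
  if (!all(pair %in% params$fitted_categories)) {
    stop(errorCondition(
      paste0("density not fitted for: ",
             paste(setdiff(pair, params$fitted_categories), collapse = ", ")),
      labels = setdiff(pair, params$fitted_categories),
      class = c("catrep_underdetermined_category", "error", "condition")
    ))
  }
  fx <- density_value(params, params$categories[[pair[1]]], stimulus)
  fy <- density_value(params, params$categories[[pair[2]]], stimulus)
  ifelse(fx + fy == 0, 0.5, fx / (fx + fy))
}

#' @export
print.density_params <- function(x, ...) {
  cat(sprintf("<density_params> mode %s, alpha = %s\n", x$mode,
              ifelse(is.na(x$alpha), "unset", format(x$alpha, digits = 4))))
  for (lab in x$fitted_categories) {
    est <- x$categories[[lab]]
    if (x$mode == "RB") {
      cat(sprintf("  %s (n=%d): mean = %.4f, var = %.5f\n",
                  lab, est$n, est$mean, est$var))
    } else {
      cat(sprintf("  %s (n=%d): mean = (%.3f, %.3f)\n",
                  lab, est$n, est$mean[1], est$mean[2]))
    }
  }
  invisible(x)
}
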