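# The between-category (boundary) observer model: one 1-D cumulative
# Gaussian per trained contrast (AB and CD), on a fixed projection axis.
# The bound's mean is its location, its SD the perceptual noise; there are
# 4 representational parameters in total.

pair_key <- function(pair) paste(sort(pair), collapse = "")

#' Fit the decision-bound parameters of the between-category model
#'
#' For each trained pair (A-B and C-D), finds the bound location `c` and
#' noise SD `sigma` maximizing the Bernoulli likelihood of the implied
#' responses under `p(respond upper label | d) = Phi((proj(d) - c) / sigma)`,
#' where `proj` projects stimuli onto the structure's fixed
#' [projection_axis()] (along which the category means are ordered
#' A < B < C < D). Optimization is deterministic: L-BFGS-B on
#' `(c, log sigma)` with the bound initialized at the midpoint of the
#' per-response-group projected means and sigma at the pooled projected SD,
#' gradient tolerance 1e-8, and `sigma` bounded below by `sigma_floor`
#' (perfectly separable responses drive it to that floor).
#'
#' @param session A `catrep_session` with responses.
#' @param trial_window Integer trial indices (default 301:500).
#' @param axis Unit 2-vector; defaults to the structure's projection axis.
#' @param sigma_floor Lower bound on the noise SD, stimulus units.
#' @return An object of class `boundary_params` with fields `axis`,
#'   `pairs` (named `AB`/`CD`, each `c`, `sigma`, `n`) and `alpha = NA`.
#' @export
fit_boundary_params <- function(session, trial_window = 301:500,
                                axis = projection_axis(session$structure_kind),
                                sigma_floor = 1e-3) {
  stopifnot(length(axis) == 2L)
  axis <- axis / sqrt(sum(axis^2))
  window <- session$trials[session$trials$trial %in% trial_window, ,
                           drop = FALSE]
  fits <- list()
  for (pair in list(c("A", "B"), c("C", "D"))) {
    sel <- select_fitting_trials(session, "boundary", pair, trials = window)
    sel <- sel[sel$implied_category %in% pair, , drop = FALSE]
    key <- pair_key(pair)
    if (nrow(sel) == 0L || length(unique(sel$implied_category)) < 2L) {
      stop(errorCondition(
        paste0("non-identifiable ", key, " bound: all implied responses ",
               "identical (or no usable trials)."),
        pair = key,
        class = c("catrep_nonidentifiable_bound", "error", "condition")
      ))
    }
    proj <- cbind(sel$dim1, sel$dim2) %*% axis
    y <- as.numeric(sel$implied_category == pair[2])  # upper label on axis
    nll <- function(par) {
      z <- (proj - par[1]) / exp(par[2])
      -sum(y * stats::pnorm(z, log.p = TRUE) +
             (1 - y) * stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
    }
    c0 <- (mean(proj[y == 1]) + mean(proj[y == 0])) / 2
    s0 <- max(stats::sd(proj), sigma_floor * 10)
    r <- max(diff(range(proj)), sigma_floor)
    opt <- stats::optim(
      c(c0, log(s0)), nll, method = "L-BFGS-B",
      lower = c(min(proj) - r, log(sigma_floor)),
      upper = c(max(proj) + r, log(100 * max(r, 1))),
      control = list(pgtol = 1e-8, maxit = 500)
    )
    fits[[key]] <- list(c = opt$par[1], sigma = exp(opt$par[2]),
                        n = nrow(sel), loglik = -opt$value)
  }
  structure(list(axis = as.numeric(axis), pairs = fits, alpha = NA_real_),
            class = "boundary_params")
}

project_stimuli <- function(params, stimulus) {
  as.numeric(unname(rbind(stimulus)) %*% params$axis)
}

bound_cdf <- function(params, key, stimulus) {
  b <- params$pairs[[key]]
  stats::pnorm((project_stimuli(params, stimulus) - b$c) / b$sigma)
}

#' Region probability under the between-category model at training
#'
#' During training only the relevant trained bound is consulted: the
#' probability of locating a stimulus on the lower side of the pair's bound
#' is `1 - F(d)` where `F` is the bound's cumulative Gaussian evaluated at
#' the stimulus projection; the upper side gets the complement. For pair
#' (A, B), label A is the lower side; for (C, D), label C.
#'
#' @param params A `boundary_params` object.
#' @param stimulus Numeric 2-vector or n x 2 matrix.
#' @param pair Length-2 label vector (a trained pair); the returned
#'   probability is for the first element.
#' @return `p(C_X | d)` vectorized over stimulus rows.
#' @export
boundary_region_prob_train <- function(params, stimulus, pair) {
  stopifnot(inherits(params, "boundary_params"), length(pair) == 2L)
  key <- pair_key(pair)
  if (!key %in% names(params$pairs)) {
    stop("no ", key, " bound was trained.", call. = FALSE)
  }
  f <- bound_cdf(params, key, stimulus)
  lower <- sort(pair)[1]
  if (pair[1] == lower) 1 - f else f
}

#' Region probability under the between-category model at test
#'
#' There is no trained B-C bound, so the test-phase B-region probability
#' combines both trained bounds:
#' `p(C_B | d) = F_AB(d) / (F_AB(d) + (1 - F_CD(d)))` -- the numerator is
#' the probability of "B" according to the AB bound, and the denominator
#' normalizes by the probability of "C" according to the CD bound.
#' `p(C_C | d)` is the complement. When both terms vanish the convention is
#' 0.5 (maximum ignorance).
#'
#' @param params A `boundary_params` object.
#' @param stimulus Numeric 2-vector or n x 2 matrix.
#' @return `p(C_B | d)` vectorized over stimulus rows.
#' @export
boundary_region_prob_test <- function(params, stimulus) {
  stopifnot(inherits(params, "boundary_params"))
  f_ab <- bound_cdf(params, "AB", stimulus)
  one_minus_f_cd <- stats::pnorm(
    (project_stimuli(params, stimulus) - params$pairs$CD$c) /
      params$pairs$CD$sigma,
    lower.tail = FALSE
  )
  denom <- f_ab + one_minus_f_cd
  ifelse(denom == 0, 0.5, f_ab / denom)
}

#' @export
print.boundary_params <- function(x, ...) {
  cat(sprintf("<boundary_params> axis = (%.3f, %.3f), alpha = %s\n",
              x$axis[1], x$axis[2],
              ifelse(is.na(x$alpha), "unset", format(x$alpha, digits = 4))))
  for (key in names(x$pairs)) {
    b <- x$pairs[[key]]
    cat(sprintf("  %s bound (n=%d): c = %.4f, sigma = %.4f\n",
                key, b$n, b$c, b$sigma))
  }
  invisible(x)
}
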