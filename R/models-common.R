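# Observer-model primitives shared by the density (within-category) and
# boundary (between-category) models: the region-probability equations,
# the softmax decision rule, the alpha (decision noise) fit, and RMSD.

#' Softmax decision rule mapping region probabilities to response probabilities
#'
#' Given the probabilities that a stimulus lies in the perceptual region of
#' category X versus the contrasting category Y, the probability of actually
#' responding X is `exp(alpha * p_cx) / (exp(alpha * p_cx) + exp(alpha * p_cy))`.
#' `alpha` is the decision-noise parameter: 0 means pure guessing, large
#' values approach a deterministic choice of the more probable region.
#'
#' @param p_cx,p_cy Region probabilities in `[0, 1]` (vectorized).
#' @param alpha Non-negative decision-noise scalar.
#' @return Response probability `p(R_X | d)` in `[0, 1]`.
#' @export
#' @examples
#' decision_prob(1, 0, 2)  # exp(2) / (exp(2) + 1)
decision_prob <- function(p_cx, p_cy, alpha) {
  stopifnot(alpha >= 0, all(p_cx >= 0 & p_cx <= 1), all(p_cy >= 0 & p_cy <= 1))
  1 / (1 + exp(-alpha * (p_cx - p_cy)))
}

#' Fit the decision-noise parameter alpha by least squares
#'
#' Minimizes `SSE(alpha) = sum_i (y_i - p(R_X | d_i; alpha))^2` over
#' `alpha` in `[0, 50]` by deterministic bounded scalar search
#' (tolerance 1e-6), where `y_i` is the observed 0/1 indicator that the
#' participant's implied response was X and the region probabilities are
#' held fixed. The interval endpoints are also evaluated so a boundary
#' optimum is returned exactly.
#'
#' @param p_cx,p_cy Region probabilities per trial.
#' @param y 0/1 observed response indicators (same length).
#' @param upper Upper search bound for alpha.
#' @return List with `alpha` and `sse`.
#' @export
fit_alpha <- function(p_cx, p_cy, y, upper = 50) {
  stopifnot(length(p_cx) == length(y), length(p_cy) == length(y),
            length(y) >= 1L, all(y %in% c(0, 1)))
  sse <- function(alpha) sum((y - decision_prob(p_cx, p_cy, alpha))^2)
  opt <- stats::optimize(sse, interval = c(0, upper), tol = 1e-6)
  cand_alpha <- c(opt$minimum, 0, upper)
  cand_sse <- c(opt$objective, sse(0), sse(upper))
  best <- which.min(cand_sse)
  list(alpha = cand_alpha[best], sse = cand_sse[best])
}

#' Root mean square deviation between predictions and observed responses
#'
#' `sqrt(mean((y - p)^2))`; used as the generalization error of a model on
#' the transfer test, with parameters frozen from the training fit.
#'
#' @param y Observed 0/1 indicators.
#' @param p Predicted response probabilities.
#' @return Non-negative scalar.
#' @export
rmsd <- function(y, p) {
  if (length(y) == 0L) stop("rmsd needs at least one trial.", call. = FALSE)
  stopifnot(length(y) == length(p))
  sqrt(mean((y - p)^2))
}

#' Select the trials a model component is fitted on
#'
#' Encodes the trial-selection rules of the two observer models. Density
#' model, Yes/No condition: the density of category X is estimated only
#' from trials where the question named X and the participant answered
#' "yes" (a "no" does not reveal which category they had in mind). Density
#' model, A/B condition: all trials on which button X was pressed,
#' regardless of the question. Boundary model: all trials whose question
#' involved the pair (Yes/No: the named target is in the pair; A/B: the
#' pressed button is in the pair).
#'
#' @param session A `catrep_session` with responses.
#' @param model `"density"` or `"boundary"`.
#' @param key A single category label (density) or a length-2 label vector
#'   (boundary).
#' @param trials Trial subset to select from (defaults to all trials);
#'   pass e.g. `session$trials[301:500, ]` to restrict to a fit window.
#' @return The selected rows of the trial table (possibly zero rows).
#' @export
select_fitting_trials <- function(session, model = c("density", "boundary"),
                                  key, trials = session$trials) {
  model <- match.arg(model)
  answered <- vapply(trials$response, is_category_response, logical(1),
                     condition = session$condition)
  trials <- trials[answered, , drop = FALSE]
  if (model == "density") {
    stopifnot(length(key) == 1L, key %in% cat_labels)
    if (session$condition == "YN") {
      sel <- trials$question == paste0("is:", key) & trials$response == "yes"
    } else {
      sel <- trials$implied_category == key
    }
  } else {
    stopifnot(length(key) == 2L, all(key %in% cat_labels))
    if (session$condition == "YN") {
      sel <- sub("^is:", "", trials$question) %in% key
    } else {
      sel <- trials$implied_category %in% key
    }
  }
  trials[sel, , drop = FALSE]
}
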