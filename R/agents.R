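# Synthetic observers. These are not models of human learning: they are
# agents constructed to respond from exactly one of the two representations
# the analysis distinguishes, so that model recovery can be scored against
# a known ground truth.

#' Configure a synthetic observer
#'
#' A `"within"` agent maintains running per-category Gaussian estimates
#' (bivariate mean and covariance, updated from feedback) and responds via
#' the density-ratio region probability; a `"between"` agent maintains only
#' one criterion per trained pair on the structure's projection axis (the
#' midpoint of the per-side running projected means) plus a perceptual
#' noise SD, and responds via the bound cumulative-Gaussian probabilities
#' -- at test it must combine the two trained bounds, which is what limits
#' it to chance transfer. Both agents pass their region probability through
#' the softmax decision rule with noise `alpha_agent`, and guess uniformly
#' for the first `learn_burnin` trials or while estimates are undefined.
#'
#' @param representation `"within"` or `"between"`.
#' @param alpha_agent Decision-noise scalar >= 0 (0 = pure guessing).
#' @param learn_burnin Number of initial trials answered by guessing
#'   (0-500).
#' @param sigma_agent Perceptual noise SD of the between-agent's bounds, in
#'   projected stimulus units. The default (0.02, a fifth of the RB
#'   within-category SD) models a sharp criterion: training responses stay
#'   near-optimal while the test-phase combined-bounds probabilities remain
#'   close to 0.5, i.e. chance-level transfer.
#' @param seed Integer seed for the agent's response stream.
#' @return An `agent_config` object.
#' @export
agent_config <- function(representation = c("within", "between"),
                         alpha_agent = 20, learn_burnin = 50,
                         sigma_agent = 0.02, seed = 1L) {
  representation <- match.arg(representation)
  if (!is.numeric(alpha_agent) || alpha_agent < 0) {
    stop("`alpha_agent` must be >= 0.", call. = FALSE)
  }
  if (learn_burnin < 0 || learn_burnin > 500) {
    stop("`learn_burnin` must lie in [0, 500].", call. = FALSE)
  }
  if (sigma_agent <= 0) stop("`sigma_agent` must be > 0.", call. = FALSE)
  structure(list(representation = representation,
                 alpha_agent = alpha_agent,
                 learn_burnin = as.integer(learn_burnin),
                 sigma_agent = sigma_agent, seed = as.integer(seed)),
            class = "agent_config")
}

#' Simulate an observer through a session schedule
#'
#' Fills the responses of an empty schedule with the behavior of a
#' synthetic observer (see [agent_config()]). On every training trial the
#' question plus the feedback uniquely identify the stimulus's true
#' category, so agents update their internal estimates with the true label
#' regardless of what they answered; at test there is no feedback and no
#' updating. Deterministic given the agent seed.
#'
#' @param schedule A `catrep_session` with empty responses
#'   (from [build_schedule()]).
#' @param agent An `agent_config`.
#' @return The completed `catrep_session`, with the agent configuration
#'   attached as `$agent` (its `representation` is the ground-truth tag for
#'   model recovery).
#' @export
simulate_session <- function(schedule, agent) {
  stopifnot(inherits(schedule, "catrep_session"), inherits(agent, "agent_config"))
  if (any(schedule$trials$response != "none")) {
    stop("schedule already contains responses.", call. = FALSE)
  }
  tr <- schedule$trials
  condition <- schedule$condition
  axis <- projection_axis(schedule$structure_kind)
  n_trials <- nrow(tr)

  # within-agent state: per-category running mean and scatter (Welford)
  w_state <- lapply(cat_labels, function(...) {
    list(n = 0, mean = c(0, 0), m2 = matrix(0, 2, 2))
  })
  names(w_state) <- cat_labels
  # between-agent state: per pair, per-side running projected means
  b_state <- list(AB = list(), CD = list())

  w_update <- function(lab, x) {
    st <- w_state[[lab]]
    st$n <- st$n + 1
    delta <- x - st$mean
    st$mean <- st$mean + delta / st$n
    st$m2 <- st$m2 + outer(delta, x - st$mean)
    w_state[[lab]] <<- st
  }
  w_density <- function(lab, x) {
    st <- w_state[[lab]]
    if (st$n < 3) return(NA_real_)
    cv <- st$m2 / (st$n - 1)
    diag(cv) <- pmax(diag(cv), 1e-6)
    dt <- det(cv)
    if (dt <= 1e-12) return(NA_real_)
    centered <- x - st$mean
    q <- sum(centered * solve(cv, centered))
    exp(-q / 2) / (2 * pi * sqrt(dt))
  }
  b_update <- function(lab, proj) {
    key <- if (lab %in% c("A", "B")) "AB" else "CD"
    side <- b_state[[key]][[lab]]
    if (is.null(side)) side <- c(n = 0, sum = 0)
    side["n"] <- side["n"] + 1
    side["sum"] <- side["sum"] + proj
    b_state[[key]][[lab]] <<- side
  }
  b_criterion <- function(key) {
    sides <- b_state[[key]]
    if (length(sides) < 2L) return(NA_real_)
    means <- vapply(sides, function(s) s[["sum"]] / s[["n"]], numeric(1))
    mean(means)
  }

  responses <- character(n_trials)
  implied <- character(n_trials)

  withr::with_seed(agent$seed, {
    for (i in seq_len(n_trials)) {
      pair <- question_pair(tr$question[i], tr$phase[i])
      x <- c(tr$dim1[i], tr$dim2[i])
      p_cx <- NA_real_
      if (i > agent$learn_burnin) {
        if (agent$representation == "within") {
          fx <- w_density(pair[1], x)
          fy <- w_density(pair[2], x)
          if (!is.na(fx) && !is.na(fy) && fx + fy > 0) p_cx <- fx / (fx + fy)
        } else {
          proj <- sum(axis * x)
          if (tr$phase[i] == "train") {
            key <- if (pair[1] %in% c("A", "B")) "AB" else "CD"
            cc <- b_criterion(key)
            if (!is.na(cc)) {
              f <- stats::pnorm((proj - cc) / agent$sigma_agent)
              lower <- sort(pair)[1]
              p_cx <- if (pair[1] == lower) 1 - f else f
            }
          } else {
            c_ab <- b_criterion("AB")
            c_cd <- b_criterion("CD")
            if (!is.na(c_ab) && !is.na(c_cd)) {
              f_ab <- stats::pnorm((proj - c_ab) / agent$sigma_agent)
              one_minus_f_cd <- stats::pnorm((proj - c_cd) / agent$sigma_agent,
                                             lower.tail = FALSE)
              denom <- f_ab + one_minus_f_cd
              p_b <- if (denom == 0) 0.5 else f_ab / denom
              p_cx <- if (pair[1] == "B") p_b else 1 - p_b
            }
          }
        }
      }
      p_respond_x <- if (is.na(p_cx)) 0.5 else {
        decision_prob(p_cx, 1 - p_cx, agent$alpha_agent)
      }
      chosen <- if (stats::runif(1) < p_respond_x) pair[1] else pair[2]
      implied[i] <- chosen
      responses[i] <- if (condition == "AB") chosen else {
        if (chosen == sub("^is:", "", tr$question[i])) "yes" else "no"
      }
      if (tr$phase[i] == "train") {
        # feedback + question reveal the true label; update from it
        if (agent$representation == "within") {
          w_update(tr$true_category[i], x)
        } else {
          b_update(tr$true_category[i], sum(axis * x))
        }
      }
    }
  })

  tr$response <- responses
  tr$implied_category <- implied
  tr$correct <- as.integer(implied == tr$true_category)
  tr$feedback_given <- as.integer(tr$phase == "train")
  schedule$trials <- tr
  schedule$agent <- unclass(agent)
  validate_session(schedule)
  schedule
}

#' Simulate a cohort of synthetic observers
#'
#' Builds an independent schedule and agent per participant and simulates
#' them. The master seed expands into per-participant (schedule, agent)
#' seed pairs by drawing `2 * n` integers under the master seed, in
#' participant order -- the scheme is recorded in the cohort metadata, and
#' the whole cohort is reproducible from the master seed alone.
#'
#' @param structure_kind `"RB"` or `"II"`.
#' @param condition `"AB"` or `"YN"`.
#' @param n_within,n_between Number of within- and between-representation
#'   agents (total >= 1).
#' @param agent_defaults Named list overriding [agent_config()] defaults
#'   (`alpha_agent`, `learn_burnin`, `sigma_agent`).
#' @param seed Master integer seed.
#' @return A `catrep_cohort`; each session's `$agent$representation` is the
#'   ground-truth tag.
#' @export
simulate_cohort <- function(structure_kind = c("RB", "II"),
                            condition = c("AB", "YN"),
                            n_within = 15, n_between = 15,
                            agent_defaults = list(), seed = 1L) {
  structure_kind <- match.arg(structure_kind)
  condition <- match.arg(condition)
  n_total <- n_within + n_between
  if (n_total < 1L) {
    stop("at least one agent is required (n_within + n_between >= 1).",
         call. = FALSE)
  }
  structure <- category_structure(structure_kind)
  reps <- rep(c("within", "between"), c(n_within, n_between))
  sub_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, 2 * n_total))
  sessions <- vector("list", n_total)
  counters <- c(within = 0L, between = 0L)
  for (i in seq_len(n_total)) {
    counters[reps[i]] <- counters[reps[i]] + 1L
    pid <- sprintf("%s_%s_%s%02d", structure_kind, condition,
                   substr(reps[i], 1, 1), counters[reps[i]])
    schedule <- build_schedule(structure, condition,
                               seed = sub_seeds[2 * i - 1],
                               participant_id = pid)
    agent_args <- utils::modifyList(
      agent_defaults,
      list(representation = reps[i], seed = sub_seeds[2 * i])
    )
    agent <- do.call(agent_config, agent_args)
    sessions[[i]] <- simulate_session(schedule, agent)
  }
  new_cohort(sessions, metadata = list(
    structure = structure_kind, condition = condition, master_seed = seed,
    seed_scheme = "2n draws of sample.int under master seed; participant i uses draws (2i-1, 2i) for (schedule, agent)",
    n_within = n_within, n_between = n_between
  ))
}
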