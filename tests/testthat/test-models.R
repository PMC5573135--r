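# Helper: boundary parameters built directly, for forced-case checks.
make_bparams <- function(c_ab, s_ab, c_cd, s_cd, axis = c(0, 1)) {
  structure(list(axis = axis,
                 pairs = list(AB = list(c = c_ab, sigma = s_ab, n = 0L),
                              CD = list(c = c_cd, sigma = s_cd, n = 0L)),
                 alpha = NA_real_),
            class = "boundary_params")
}

test_that("trial selection implements the yes-only and pressed-button rules", {
  yn <- sim_session("RB", "YN", "within", seed = 51)
  sel <- select_fitting_trials(yn, "density", "A")
  expect_true(all(sel$question == "is:A"))
  expect_true(all(sel$response == "yes"))
  expect_equal(nrow(sel),
               sum(yn$trials$question == "is:A" & yn$trials$response == "yes"))
  pair_sel <- select_fitting_trials(yn, "boundary", c("C", "D"))
  expect_true(all(sub("^is:", "", pair_sel$question) %in% c("C", "D")))

  ab <- sim_session("RB", "AB", "within", seed = 52)
  sel_a <- select_fitting_trials(ab, "density", "A")
  expect_true(all(sel_a$implied_category == "A"))
  # pressed-button rule ignores the question: a B|C test trial answered "B"
  # contributes to the B density
  sel_b <- select_fitting_trials(ab, "density", "B")
  expect_true(any(sel_b$phase == "test"))

  # a participant who never presses a button yields an empty set
  stubborn <- respond_with_policy(
    build_schedule(rb_structure, "AB", seed = 53),
    function(pair, x, phase, true_label) if ("A" %in% pair) "A" else "C")
  expect_equal(nrow(select_fitting_trials(stubborn, "density", "B")), 0L)
})

test_that("density fitting recovers generative parameters by sample moments", {
  gen <- c(A = 0.30, B = 0.67, C = 1.03, D = 1.40)
  for (cond in c("YN", "AB")) {
    s <- sim_session("RB", cond, "within", seed = 54)
    dp <- fit_density_params(s)
    for (lab in names(gen)) {
      est <- dp$categories[[lab]]
      if (est$n >= 20) expect_lt(abs(est$mean - gen[[lab]]), 0.08)
    }
  }
  # II mode fits bivariate means
  s2 <- sim_session("II", "AB", "within", seed = 55)
  dp2 <- fit_density_params(s2)
  expect_equal(dp2$mode, "II")
  expect_lt(max(abs(dp2$categories$B$mean - c(1.50, 1.93))), 0.15)
  expect_equal(dim(dp2$categories$B$cov), c(2L, 2L))
})

test_that("density fitting floors degenerate variance and flags missing categories", {
  s <- sim_session("RB", "AB", "within", seed = 56)
  # all selected trials identical: constant stimuli within the window
  frozen <- s
  frozen$trials$dim2[frozen$trials$trial %in% 301:500] <- 0.7
  dp <- fit_density_params(frozen)
  expect_equal(dp$categories$B$var, 1e-4)

  stubborn <- respond_with_policy(
    build_schedule(rb_structure, "AB", seed = 57),
    function(pair, x, phase, true_label) if ("A" %in% pair) "A" else "C")
  err <- tryCatch(fit_density_params(stubborn),
                  catrep_underdetermined_category = identity)
  expect_s3_class(err, "catrep_underdetermined_category")
  expect_true(all(c("B", "D") %in% err$labels))
})

test_that("density region probabilities follow the density-ratio rule", {
  dp <- structure(list(
    mode = "RB",
    categories = list(A = list(n = 100, mean = 0.30, var = 0.01),
                      B = list(n = 100, mean = 0.67, var = 0.01)),
    alpha = NA_real_, fitted_categories = c("A", "B"), var_floor = 1e-4),
    class = "density_params")
  # stimulus at the B mean: odds against A are exp((0.37^2) / (2 * 0.01))
  expect_equal(density_region_prob(dp, c(1.9, 0.67), c("B", "A")),
               1 / (1 + exp(-0.37^2 / 0.02)), tolerance = 1e-9)
  expect_equal(round(density_region_prob(dp, c(1.9, 0.67), c("B", "A")), 4),
               0.9989)
  # equidistant stimulus between equal-variance densities
  expect_equal(density_region_prob(dp, c(1.9, 0.485), c("A", "B")), 0.5)
  # complement identity
  stim <- cbind(1.9, seq(0, 1.5, by = 0.1))
  expect_equal(density_region_prob(dp, stim, c("A", "B")) +
                 density_region_prob(dp, stim, c("B", "A")),
               rep(1, nrow(stim)))
  # f_Y = 0 with f_X > 0 forces 1; both underflowing gives 0.5
  expect_equal(density_region_prob(dp, c(1.9, 2), c("B", "A")), 1)
  expect_equal(density_region_prob(dp, c(1.9, 1e6), c("A", "B")), 0.5)
  expect_error(density_region_prob(dp, c(1.9, 0.5), c("C", "B")),
               class = "catrep_underdetermined_category")
})

test_that("the generative density model implies the optimal midpoint bound", {
  # equal-variance Gaussians: the decision flips exactly at the mean midpoint
  dp <- structure(list(
    mode = "RB",
    categories = list(A = list(n = 100, mean = 0.30, var = 0.01),
                      B = list(n = 100, mean = 0.67, var = 0.01)),
    alpha = NA_real_, fitted_categories = c("A", "B"), var_floor = 1e-4),
    class = "density_params")
  midpoint <- (0.30 + 0.67) / 2
  expect_equal(density_region_prob(dp, c(1.9, midpoint), c("B", "A")), 0.5)
  expect_lt(density_region_prob(dp, c(1.9, midpoint - 1e-6), c("B", "A")), 0.5)
  expect_gt(density_region_prob(dp, c(1.9, midpoint + 1e-6), c("B", "A")), 0.5)
})

test_that("boundary region probabilities: training bound and test combination", {
  bp <- make_bparams(c_ab = 0.485, s_ab = 0.1, c_cd = 1.215, s_cd = 0.1)
  # stimulus at the bound location: either side equally likely
  expect_equal(boundary_region_prob_train(bp, c(1.9, 0.485), c("A", "B")), 0.5)
  # far stimuli saturate monotonically
  dim2 <- seq(0.485, 1.0, by = 0.05)
  p_b <- boundary_region_prob_train(bp, cbind(1.9, dim2), c("B", "A"))
  expect_true(all(diff(p_b) > 0))
  expect_gt(p_b[length(p_b)], 0.999999)
  # complement identity at train and test
  stim <- cbind(1.9, seq(0, 1.7, by = 0.1))
  expect_equal(boundary_region_prob_train(bp, stim, c("A", "B")) +
                 boundary_region_prob_train(bp, stim, c("B", "A")),
               rep(1, nrow(stim)))

  # symmetric point: F_AB = 1 - F_CD midway between the two bounds
  expect_equal(boundary_region_prob_test(bp, c(1.9, 0.85)), 0.5)
  # F_CD = 1 and F_AB = 0.5 force p(C_B) = 1
  bp2 <- make_bparams(c_ab = 1.0, s_ab = 0.1, c_cd = -5, s_cd = 0.1)
  expect_equal(boundary_region_prob_test(bp2, c(1.9, 1.0)), 1.0)
  # degenerate 0/0 falls back to maximum ignorance
  bp3 <- make_bparams(c_ab = 10, s_ab = 1e-3, c_cd = -10, s_cd = 1e-3)
  expect_equal(boundary_region_prob_test(bp3, c(1.9, 0.85)), 0.5)
})

test_that("softmax decision rule: forced cases and monotonicity", {
  expect_equal(decision_prob(0.9, 0.1, 0), 0.5)
  expect_equal(decision_prob(0.42, 0.42, 17), 0.5)
  expect_equal(decision_prob(1, 0, 2), exp(2) / (exp(2) + 1))
  expect_equal(round(decision_prob(1, 0, 2), 4), 0.8808)
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(decision_prob(p, 0.3, 5)) > 0))
  # only the difference of region probabilities matters
  expect_equal(decision_prob(0.7, 0.2, 3), decision_prob(0.9, 0.4, 3))
})

test_that("alpha fitting matches a brute-force grid and handles edge cases", {
  grid_alpha <- function(p_cx, p_cy, y, step = 1e-3) {
    alphas <- seq(0, 50, by = step)
    sses <- vapply(alphas, function(a) {
      sum((y - decision_prob(p_cx, p_cy, a))^2)
    }, numeric(1))
    list(alpha = alphas[which.min(sses)], sse = min(sses))
  }
  for (seed in 1:3) {
    set.seed(seed)
    p <- runif(100)
    true_alpha <- runif(1, 1, 20)
    y <- rbinom(100, 1, decision_prob(p, 1 - p, true_alpha))
    got <- fit_alpha(p, 1 - p, y)
    want <- grid_alpha(p, 1 - p, y)
    expect_lt(abs(got$alpha - want$alpha), 1e-3)
    expect_lte(got$sse, want$sse + 1e-9)
  }
  # responses independent of the region probabilities: alpha collapses to 0
  set.seed(99)
  p <- runif(1000)
  y <- rbinom(1000, 1, 0.5)
  fair <- fit_alpha(p, 1 - p, y)
  expect_equal(fair$alpha, 0)
  expect_equal(fair$sse, sum((y - 0.5)^2))
  # a single informative trial saturates alpha at the search bound
  one <- fit_alpha(0.8, 0.2, 1)
  expect_equal(one$alpha, 50)
  sse_grid <- vapply(seq(0, 50, by = 0.5), function(a) {
    (1 - decision_prob(0.8, 0.2, a))^2
  }, numeric(1))
  expect_true(all(diff(sse_grid) < 0))
})

test_that("boundary fitting recovers a known response policy", {
  set.seed(7)
  session <- respond_with_policy(
    build_schedule(rb_structure, "AB", seed = 5),
    function(pair, x, phase, true_label) {
      cc <- if (all(pair %in% c("A", "B"))) 0.85 else 1.215
      if (runif(1) < pnorm((x[2] - cc) / 0.1)) sort(pair)[2] else sort(pair)[1]
    })
  bp <- fit_boundary_params(session, trial_window = 1:500)
  expect_lt(abs(bp$pairs$AB$c - 0.85), 0.05)
  expect_lt(abs(bp$pairs$AB$sigma - 0.1) / 0.1, 0.5)
  expect_lt(abs(bp$pairs$CD$c - 1.215), 0.05)

  # independent oracle: probit regression gives the same MLE
  w <- session$trials[session$trials$trial <= 500 &
                        session$trials$implied_category %in% c("A", "B"), ]
  g <- suppressWarnings(glm(I(implied_category == "B") ~ dim2,
                            family = binomial("probit"), data = w))
  expect_equal(bp$pairs$AB$c, -coef(g)[[1]] / coef(g)[[2]], tolerance = 1e-3)
  expect_equal(bp$pairs$AB$sigma, 1 / coef(g)[[2]], tolerance = 1e-3)
})

test_that("boundary fitting handles separable and degenerate responses", {
  # deterministic criterion responses: perfectly separable
  session <- respond_with_policy(
    build_schedule(rb_structure, "AB", seed = 6),
    function(pair, x, phase, true_label) {
      cc <- if (all(pair %in% c("A", "B"))) 0.485 else 1.215
      if (x[2] > cc) sort(pair)[2] else sort(pair)[1]
    })
  bp <- fit_boundary_params(session, trial_window = 1:500)
  # the likelihood is flat once separation is perfect: sigma is driven to
  # (near) the configured floor
  expect_lt(bp$pairs$AB$sigma, 5e-3)
  expect_gte(bp$pairs$AB$sigma, 1e-3)
  proj <- session$trials$dim2[session$trials$trial <= 500]
  expect_gt(bp$pairs$AB$c, min(proj))
  expect_lt(bp$pairs$AB$c, max(proj))

  # all responses identical within a pair: the bound is non-identifiable
  stubborn <- respond_with_policy(
    build_schedule(rb_structure, "AB", seed = 8),
    function(pair, x, phase, true_label) if ("A" %in% pair) "A" else "C")
  expect_error(fit_boundary_params(stubborn, trial_window = 1:500),
               class = "catrep_nonidentifiable_bound")
})

test_that("rmsd follows its closed form", {
  expect_equal(rmsd(c(1, 0, 1), c(1, 0, 1)), 0)
  y <- rbinom(50, 1, 0.5)
  expect_equal(rmsd(y, rep(0.5, 50)), 0.5)
  expect_equal(rmsd(c(1, 0, 1), c(0.9, 0.2, 0.6)), sqrt(0.21 / 3))
  expect_equal(round(rmsd(c(1, 0, 1), c(0.9, 0.2, 0.6)), 4), 0.2646)
  expect_error(rmsd(numeric(0), numeric(0)), "at least one")
})
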