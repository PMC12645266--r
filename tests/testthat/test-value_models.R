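test_that("model catalog spans the 3 x 2 x 2 grid with canonical names", {
  cat12 <- model_catalog()
  expect_length(cat12, 12)
  expect_false(anyDuplicated(cat12) > 0)
  m <- model_spec("parabolic_2k1b")
  expect_true(m$two_kappa)
  expect_false(m$two_beta)
  expect_identical(model_spec(shape = "parabolic", n_kappa = 2)$name,
                   "parabolic_2k1b")
  expect_error(model_spec("quadratic_1k1b"), "unknown model")
})

test_that("subjective value follows the three discount shapes", {
  # kappa = 0 collapses every shape to SV = Shock
  for (shape in c("linear", "parabolic", "hyperbolic")) {
    expect_equal(subjective_value(shape, 0, -3, 4), -3)
  }
  # parabolic at the printed group-mean discount rate
  expect_equal(subjective_value("parabolic", -0.19, -1, 5), -5.75)
  # linear boundary: work offer exactly matches the rest offer value
  expect_equal(subjective_value("linear", -1, -1, 5), -6)
  # hyperbolic domain: denominator must stay positive
  expect_error(subjective_value("hyperbolic", -0.25, -3, 5), "denominator")
  expect_error(subjective_value("linear", 0, -6, 3), "shock")
  expect_error(subjective_value("linear", 0, -3, 6), "effort")
})

test_that("softmax choice rule is normalized, symmetric and overflow-safe", {
  expect_equal(choice_probability(-6, beta = 3), 0.5)       # sv_work = sv_rest
  expect_equal(choice_probability(-2, beta = 0), 0.5)       # pure-noise limit
  expect_equal(choice_probability(-5.75, beta = 2),
               1 / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(choice_probability(-1, beta = 1e8), 1)       # no overflow
  expect_equal(choice_probability(-300, beta = 1e8), 0)
  # strictly increasing in sv_work and in beta when work beats rest
  p <- choice_probability(seq(-5.9, -1, 0.1), beta = 2)
  expect_true(all(diff(p) > 0))
  p_beta <- vapply(c(0.5, 1, 2, 4), function(b) choice_probability(-4, b),
                   numeric(1))
  expect_true(all(diff(p_beta) > 0))
})

test_that("trial log-likelihood matches first-principles arithmetic", {
  # 10-trial toy set recomputed with explicit formulas (no package calls)
  set.seed(42)
  trials <- data.frame(
    recipient = rep(c("self", "other"), 5),
    effort_level = sample(1:5, 10, replace = TRUE),
    work_shocks = sample(1:5, 10, replace = TRUE),
    choice = sample(c("work", "rest"), 10, replace = TRUE))
  params <- parameter_set(kappa_self = -0.19, kappa_effect = 0.02,
                          beta_self = 2)
  model <- model_spec("parabolic_2k1b")
  ll <- trial_loglik(params, trials, model)

  oracle <- vapply(seq_len(10), function(i) {
    k <- if (trials$recipient[i] == "other") -0.19 + 0.02 else -0.19
    sv <- -trials$work_shocks[i] + k * trials$effort_level[i]^2
    p <- 1 / (1 + exp(-2 * (sv - (-6))))
    if (trials$choice[i] == "work") log(p) else log(1 - p)
  }, numeric(1))
  expect_equal(ll, oracle, tolerance = 1e-12)
  expect_equal(dataset_loglik(params, trials, model), sum(oracle))

  # single-trial worked example: p(work) = 1/(1+exp(-0.5))
  one <- data.frame(recipient = "self", effort_level = 5, work_shocks = 1,
                    choice = "work")
  expect_equal(trial_loglik(params, one, model), log(1 / (1 + exp(-0.5))),
               tolerance = 1e-12)
})

test_that("choice probabilities normalize and kappa = 0 unifies shapes", {
  set.seed(7)
  for (rep in 1:20) {
    shape <- sample(c("linear", "parabolic", "hyperbolic"), 1)
    kappa <- if (shape == "hyperbolic") runif(1, -0.19, 0) else runif(1, -1, 0)
    params <- parameter_set(kappa_self = kappa, beta_self = runif(1, 0.1, 5))
    tr <- data.frame(recipient = sample(c("self", "other"), 1),
                     effort_level = sample(1:5, 1),
                     work_shocks = sample(1:5, 1), choice = "work")
    model <- model_spec(shape = shape, n_kappa = 1, n_beta = 1)
    lw <- trial_loglik(params, tr, model)
    tr$choice <- "rest"
    lr <- trial_loglik(params, tr, model)
    expect_equal(exp(lw) + exp(lr), 1, tolerance = 1e-12)
  }

  trials <- expand.grid(effort_level = 1:5, work_shocks = 1:5)
  trials$recipient <- "self"
  trials$choice <- "work"
  p0 <- parameter_set(kappa_self = 0, beta_self = 1.3)
  lls <- lapply(c("linear", "parabolic", "hyperbolic"), function(s)
    trial_loglik(p0, trials, model_spec(shape = s)))
  expect_equal(lls[[1]], lls[[2]])
  expect_equal(lls[[1]], lls[[3]])
})

test_that("work probability falls with effort and rises with shock reduction", {
  for (shape in c("linear", "parabolic")) {
    for (kappa in c(-0.1, -0.4)) {
      p <- outer(1:5, 1:5, function(e, s)
        choice_probability(subjective_value(shape, kappa, -s, e), beta = 2))
      expect_true(all(apply(p, 2, diff) <= 0))  # worsens with effort
      expect_true(all(apply(p, 1, diff) <= 0))  # worsens with more shocks
    }
  }
})

test_that("dominance limit: kappa = 0 with large beta makes work certain", {
  params <- parameter_set(kappa_self = 0, beta_self = 60)
  tr <- data.frame(recipient = "self", effort_level = 5, work_shocks = 5,
                   choice = "work")
  ll <- trial_loglik(params, tr, model_spec("linear_1k1b"))
  expect_gt(ll, -1e-20)  # log p -> 0: SV_work >= -5 > -6
})

test_that("parameter sets enforce the sign conventions", {
  expect_error(parameter_set(kappa_self = 0.1, beta_self = 1), "<= 0")
  expect_error(parameter_set(kappa_self = -0.1, kappa_effect = 0.3,
                             beta_self = 1), "kappa_other")
  ps <- parameter_set(kappa_self = -0.2, kappa_effect = 0.05, beta_self = 2)
  expect_equal(ps$kappa_other, -0.15)
  expect_equal(ps$beta_other, 2)
})
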