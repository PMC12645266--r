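test_that("population sampling respects constraints and is reproducible", {
  cfg <- population_config(n_subjects = 200)
  pop <- sample_population(cfg, seed = 4)
  expect_true(all(pop$kappa_self <= 0))
  expect_true(all(pop$kappa_other <= 0))
  expect_true(all(pop$beta > 0))
  expect_identical(pop, sample_population(cfg, seed = 4))

  # degenerate population: zero sigmas give identical agents
  cfg0 <- population_config(n_subjects = 5, group_sigma_kappa_self = 0,
                            group_sigma_kappa_effect = 0,
                            group_sigma_log_beta = 0)
  pop0 <- sample_population(cfg0, seed = 1)
  expect_equal(unique(pop0$kappa_self), -0.19)
  expect_equal(unique(pop0$beta), exp(cfg0$group_mu_log_beta))

  # hyperbolic shape keeps kappa inside (-0.2, 0]
  cfgh <- population_config(n_subjects = 500,
                            model = model_spec("hyperbolic_2k1b"))
  poph <- sample_population(cfgh, seed = 2)
  expect_true(all(poph$kappa_self > -0.2 & poph$kappa_self <= 0))
  expect_true(all(poph$kappa_other > -0.2))
})

test_that("resampled kappa matches the truncated-normal mean", {
  # oracle: closed-form mean of N(-0.19, 0.14) truncated to (-inf, 0]:
  # mu - sigma * dnorm(a) / pnorm(a), a = (0 - mu) / sigma
  a <- 0.19 / 0.14
  mu_trunc <- -0.19 - 0.14 * dnorm(a) / pnorm(a)
  sd_trunc <- 0.14 * sqrt(1 + (-a) * dnorm(a) / pnorm(a) -
                            (dnorm(a) / pnorm(a))^2)
  pop <- sample_population(population_config(n_subjects = 10000), seed = 8)
  se <- sd_trunc / sqrt(10000)
  expect_lt(abs(mean(pop$kappa_self) - mu_trunc), 3 * se)
})

test_that("simulated datasets obey the outcome contingencies", {
  fx <- make_cohort(n_subjects = 6, n_per_recipient = 25, seed = 3)
  d <- fx$data
  expect_s3_class(d, "ep_dataset")
  expect_equal(nrow(d), 6 * 50)
  # delivered shocks conservation
  expect_true(all(d$delivered_shocks %in% c(d$work_shocks, 6L, 10L)))
  expect_true(all(d$delivered_shocks[d$choice == "rest"] == 6L))
  expect_true(all(d$delivered_shocks[d$choice == "nonresponse"] == 10L))
  ws <- d$choice == "work" & d$success
  expect_true(all(d$delivered_shocks[ws] == d$work_shocks[ws]))
  expect_true(all(d$delivered_shocks[d$choice == "work" & !d$success] == 10L))
  # force fields present iff work
  expect_true(all(is.na(d$force_auc[d$choice != "work"])))
  expect_true(all(!is.na(d$force_auc[d$choice == "work"])))
  expect_true(all(is.na(d$rt_s[d$choice == "nonresponse"])))

  # guaranteed success never yields the 10-shock penalty on work trials
  set.seed(11)
  cfg1 <- population_config(n_subjects = 3, force_success_prob = 1)
  d1 <- simulate_dataset(sample_population(cfg1), fx$schedule, cfg1)
  expect_false(any(d1$delivered_shocks[d1$choice == "work"] == 10L))
})

test_that("a noiseless kappa = 0 agent always works when responding", {
  sched <- generate_schedule(25, seed = 5)
  cfg <- population_config(n_subjects = 2, group_mu_kappa_self = 0,
                           group_sigma_kappa_self = 0,
                           group_sigma_kappa_effect = 0,
                           group_mu_kappa_effect = 0,
                           group_mu_log_beta = log(50),
                           group_sigma_log_beta = 0)
  set.seed(2)
  agents <- sample_population(cfg)
  d <- simulate_dataset(agents, sched, cfg)
  responded <- d[d$choice != "nonresponse", ]
  expect_true(all(responded$choice == "work"))
})

test_that("the default cohort hits the behavioural targets", {
  fx <- make_cohort(n_subjects = 47, n_per_recipient = 75, seed = 6)
  d <- fx$data
  resp <- d[d$choice != "nonresponse", ]
  # pooled work rate brackets the observed band (exact-grid expectation
  # under the default population is ~0.65)
  expect_gt(mean(resp$choice == "work"), 0.6)
  expect_lt(mean(resp$choice == "work"), 0.8)
  # non-response, force and success levels near their configured rates
  expect_lt(mean(d$choice == "nonresponse"), 0.02)
  work <- d[d$choice == "work", ]
  expect_equal(mean(work$success), 0.925, tolerance = 0.02)
  expect_equal(mean(work$force_auc), 0.485, tolerance = 0.01)
  expect_equal(mean(d$rt_s, na.rm = TRUE), 1.23, tolerance = 0.02)
})

test_that("expected_work_rate matches a Monte-Carlo simulation", {
  exact <- expected_work_rate(-0.19, -0.17, beta = 2, shape = "parabolic")
  set.seed(9)
  grid <- expand.grid(effort = 1:5, shock = -5:-1)
  sim <- mean(replicate(200, {
    sv <- subjective_value("parabolic", sample(c(-0.19, -0.17), 1),
                           grid$shock, grid$effort)
    mean(rbinom(25, 1, choice_probability(sv, 2)))
  }))
  expect_equal(exact, sim, tolerance = 0.02)
})

test_that("simulated choices carry more likelihood at true than shifted kappa", {
  fx <- make_cohort(n_subjects = 8, n_per_recipient = 50, seed = 10)
  model <- fx$cfg$model
  delta <- vapply(seq_len(8), function(i) {
    tr <- fx$data[fx$data$subject_id == i & fx$data$choice != "nonresponse", ]
    a <- fx$agents[i, ]
    true_ll <- dataset_loglik(
      parameter_set(a$kappa_self, a$kappa_effect, a$beta), tr, model)
    shift_ll <- dataset_loglik(
      parameter_set(a$kappa_self - 0.5, a$kappa_effect, a$beta), tr, model)
    true_ll - shift_ll
  }, numeric(1))
  expect_true(all(is.finite(delta)))
  expect_gt(mean(delta), 0)
})

test_that("population configs validate their inputs", {
  expect_error(population_config(n_subjects = 1), ">= 2")
  expect_error(population_config(nonresponse_rate_self = 1.5), "\\[0, 1\\]")
  expect_error(population_config(group_sigma_kappa_self = -1), ">= 0")
  expect_error(population_config(model = "parabolic_2k1b"), "model_spec")
})
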