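toy_row <- function(subject_id, recipient, choice, rt = 1.2, force = 0.5,
                    success = TRUE, shocks = 2L) {
  data.frame(subject_id = subject_id, trial = 1L, recipient = recipient,
             effort_level = 3L, work_shocks = shocks, choice = choice,
             rt_s = if (choice == "nonresponse") NA_real_ else rt,
             force_auc = if (choice == "work") force else NA_real_,
             success = if (choice == "work") success else NA,
             delivered_shocks = switch(choice, work = shocks, rest = 6L,
                                       nonresponse = 10L))
}

test_that("behaviour summaries count rates over responded trials only", {
  rows <- rbind(
    do.call(rbind, lapply(1:4, function(i) toy_row(1, "self", "work"))),
    toy_row(1, "self", "rest"),
    toy_row(1, "other", "work"), toy_row(1, "other", "nonresponse"),
    toy_row(2, "self", "rest"), toy_row(2, "other", "work", success = FALSE))
  rows$delivered_shocks[rows$choice == "work" & !rows$success] <- 10L
  rows$trial <- seq_len(nrow(rows))
  beh <- summarize_behavior(rows)
  s1 <- beh$per_subject[beh$per_subject$subject_id == 1 &
                          beh$per_subject$recipient == "self", ]
  expect_equal(s1$work_choice_rate, 0.8)      # 4 work / 5 responded
  o1 <- beh$per_subject[beh$per_subject$subject_id == 1 &
                          beh$per_subject$recipient == "other", ]
  expect_equal(o1$n_nonresponse, 1)
  expect_equal(o1$work_choice_rate, 1)        # non-response excluded
  expect_equal(nrow(beh$flagged), 0)

  # an all-nonresponse condition is flagged, not NaN-propagated
  rows2 <- rbind(toy_row(1, "self", "nonresponse"),
                 toy_row(1, "other", "work"))
  rows2$trial <- 1:2
  beh2 <- summarize_behavior(rows2)
  expect_equal(beh2$flagged$recipient, "self")
  f <- beh2$per_subject[beh2$per_subject$recipient == "self", ]
  expect_true(is.na(f$work_choice_rate))
})

test_that("summaries agree with the generator's configured world", {
  fx <- make_cohort(n_subjects = 30, n_per_recipient = 75, seed = 26)
  beh <- summarize_behavior(fx$data)
  g <- beh$group
  succ <- g[g$measure == "success_rate", "mean"]
  expect_equal(succ, c(0.925, 0.925), tolerance = 0.02)
  force <- g[g$measure == "mean_force_auc", "mean"]
  expect_equal(force, c(0.485, 0.485), tolerance = 0.01)
  wr <- g[g$measure == "work_choice_rate", "mean"]
  expect_true(all(wr > 0.55 & wr < 0.8))
  # other condition discounts less (kappa_effect > 0), so works more
  expect_gt(wr[g$recipient[g$measure == "work_choice_rate"] == "other"],
            wr[g$recipient[g$measure == "work_choice_rate"] == "self"] - 0.02)
})

# independent oracle: marginal likelihood under H1 by direct integration
# over the standardized effect delta with a Cauchy prior
jzs_bf10_oracle <- function(t, n, rscale) {
  nu <- n - 1
  delta <- seq(-40, 40, length.out = 200001)
  h1 <- suppressWarnings(
    sum(dt(t, nu, ncp = delta * sqrt(n)) *
          stats::dcauchy(delta, 0, rscale)) * diff(delta[1:2]))
  h1 / dt(t, nu)
}

test_that("JZS paired BF matches an independent quadrature oracle", {
  set.seed(5)
  x <- rnorm(50, 0, 1)
  y <- x + rnorm(50, 0.05, 0.4)
  bf <- jzs_paired_bf(x, y)
  oracle <- 1 / jzs_bf10_oracle(bf$t, 50, 0.707)
  expect_equal(bf$bf01, oracle, tolerance = 1e-4)

  # t = 0: null favoured, and still oracle-exact
  bf0 <- jzs_paired_bf(x, x)
  expect_gt(bf0$bf01, 1)
  expect_equal(bf0$bf01, 1 / jzs_bf10_oracle(0, 50, 0.707), tolerance = 1e-4)

  # widening the prior with small |t| strengthens the null (oracle-checked)
  bf_wide <- jzs_paired_bf(x, y, rscale = 1.414)
  expect_gt(bf_wide$bf01, bf$bf01)
  expect_equal(bf_wide$bf01, 1 / jzs_bf10_oracle(bf$t, 50, 1.414),
               tolerance = 1e-4)
})

test_that("JZS paired BF limits, symmetry and guards", {
  set.seed(6)
  x <- rnorm(40)
  y <- x + rnorm(40, 3, 0.1)   # enormous effect
  expect_lt(jzs_paired_bf(x, y)$bf01, 1e-6)
  # sign invariance of the paired difference
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(jzs_paired_bf(a, b)$bf01, jzs_paired_bf(b, a)$bf01,
               tolerance = 1e-10)
  expect_error(jzs_paired_bf(1:5, 1:4), "paired")
  expect_error(jzs_paired_bf(1:2, 2:3), "at least 3")
  expect_warning(jzs_paired_bf(c(1, 2, 3, 4), c(2, 1, 3, 5)), "fewer than 5")
})

test_that("correlation density is a proper density and BF behaves", {
  # oracle: the sampling density of r must integrate to 1 for fixed rho
  for (rho in c(0, 0.5)) {
    total <- integrate(function(r) {
      vapply(r, function(ri) effortpain:::r_density(ri, rho, 30), numeric(1))
    }, -1, 1, rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }

  set.seed(7)
  x <- rnorm(50)
  expect_equal(pearson_bf(x, x)$r, 1)
  y <- rnorm(50)
  expect_equal(pearson_bf(x, y)$r, pearson_bf(y, x)$r)

  # independent Gaussians at n = 50 give moderate null evidence on average
  bf01 <- replicate(20, pearson_bf(rnorm(50), rnorm(50))$bf01)
  expect_gt(mean(bf01), 3)

  # strong correlation flips the evidence
  z <- x + rnorm(50, 0, 0.3)
  expect_lt(pearson_bf(x, z)$bf01, 0.1)

  expect_error(pearson_bf(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_bf(1:3, 2:4), "at least 4")
})

test_that("evidence bands reproduce the interpretive categories", {
  expect_equal(bf_category(11), "strong null")
  expect_equal(bf_category(5.65), "moderate null")
  expect_equal(bf_category(3), "moderate null")
  expect_equal(bf_category(2.31), "anecdotal")
  expect_equal(bf_category(0.31), "anecdotal")
  expect_equal(bf_category(0.2), "moderate alternative")
  expect_equal(bf_category(0.05), "strong alternative")
  expect_error(bf_category(-1), "non-negative")
})
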