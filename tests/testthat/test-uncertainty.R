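test_that("Beta moment fits round-trip their moments or repair and flag", {
  f <- beta_from_moments(0.85, 0.23)
  expect_false(f$repaired)
  m <- f$shape1 / (f$shape1 + f$shape2)
  v <- f$shape1 * f$shape2 /
    ((f$shape1 + f$shape2)^2 * (f$shape1 + f$shape2 + 1))
  expect_equal(m, 0.85, tolerance = 1e-9)
  expect_equal(sqrt(v), 0.23, tolerance = 1e-9)

  # halving the variance at fixed mean doubles-ish the concentration: check
  # through the implied-moment round-trip at several dispersions
  for (sd in c(0.01, 0.05, 0.1, 0.2)) {
    g <- beta_from_moments(0.5, sd)
    expect_equal(g$shape1 / (g$shape1 + g$shape2), 0.5, tolerance = 1e-9)
    expect_equal(sqrt(g$shape1 * g$shape2 /
      ((g$shape1 + g$shape2)^2 * (g$shape1 + g$shape2 + 1))),
      sd, tolerance = 1e-9)
  }

  # dispersion at the feasibility boundary is shrunk and flagged
  r <- beta_from_moments(0.168, 0.37)
  expect_true(r$repaired)
  expect_lt(r$sd, 0.37)
  expect_equal(r$shape1 / (r$shape1 + r$shape2), 0.168, tolerance = 1e-9)

  d <- beta_from_moments(0.4, 0)
  expect_equal(d$family, "degenerate")
  expect_equal(sample_fit(d, 3), rep(0.4, 3))
  expect_error(beta_from_moments(1.2, 0.1), "\\(0,1\\)")
})

test_that("Gamma moment fits are exact in closed form", {
  f <- gamma_from_moments(309, 67)
  expect_equal(f$shape, 21.2699933169971, tolerance = 1e-12)
  expect_equal(f$scale, 14.5275080906149, tolerance = 1e-12)
  for (i in 1:10) {
    m <- runif(1, 1, 2000)
    s <- runif(1, 1, 500)
    g <- gamma_from_moments(m, s)
    expect_equal(g$shape * g$scale, m, tolerance = 1e-12)
    expect_equal(sqrt(g$shape) * g$scale, s, tolerance = 1e-12)
  }
  expect_error(gamma_from_moments(100, 0), "> 0")
})

test_that("log-normal fit matches the requested arithmetic mean", {
  f <- lognormal_from_moments(0.81, 0.1)
  expect_equal(f$meanlog, log(0.81) - 0.005, tolerance = 1e-12)
  set.seed(5)
  x <- sample_fit(f, 1e5)
  expect_equal(mean(x), 0.81, tolerance = 3 * sd(x) / sqrt(1e5) / 0.81)
  expect_error(lognormal_from_moments(-1, 0.1), "> 0")
})

test_that("fitted samplers recover tabulated moments (repaired fits excluded)", {
  b <- default_bundle()
  fits <- psa_fits(b)
  tab <- param_table(b)
  set.seed(99)
  n <- 1e4
  for (i in seq_len(nrow(tab))) {
    f <- fits[[tab$name[i]]]
    if (f$repaired || f$family == "lognormal") next
    x <- sample_fit(f, n)
    se_mean <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - tab$value[i]), 3 * se_mean)
    # asymptotic standard error of the sample sd via the fourth moment
    m4 <- mean((x - mean(x))^4)
    se_sd <- sqrt(max(m4 - var(x)^2, 0) / n) / (2 * sd(x))
    expect_lt(abs(sd(x) - tab$sd[i]), 4 * se_sd)
  }
})

test_that("PSA is seeded, reproducible, and degenerates to the base case", {
  b <- default_bundle()
  p1 <- run_psa(b, n_draws = 40, seed = 123)
  p2 <- run_psa(b, n_draws = 40, seed = 123)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$params, p2$params)
  expect_equal(nrow(p1$draws), 40)
  expect_true(length(p1$repaired_fits) > 0)   # several tabulated SDs sit at the bound

  # zero-dispersion bundle: every draw equals the deterministic base case
  b0 <- b
  b0$transition_sds[] <- 0
  b0$cost_sds$BNP[] <- 0
  b0$cost_sds$STANDARD[] <- 0
  b0$utility_sds[] <- 0
  b0$effect$rr_log_sd <- 0
  p0 <- run_psa(b0, n_draws = 5, seed = 1)
  base <- run_cea(b0)
  expect_equal(p0$draws$delta_cost, rep(base$delta_cost, 5))
  expect_equal(p0$draws$delta_qaly, rep(base$delta_qaly, 5))
})

test_that("CEAC probabilities come from net-benefit counting over draws", {
  # hand-built draws spanning all four CE-plane quadrants
  hand <- structure(list(draws = data.frame(
    draw = 1:4,
    delta_cost = c(-100, -100, 200, 200),
    delta_qaly = c(0.1, -0.1, 0.1, -0.1)
  )), class = "psa_draws")
  cv <- ceac(hand, c(0, 1000, 5000, 1e7))
  # wtp 0: NMB = -delta_cost -> draws 1 and 2
  expect_equal(cv$prob_ce[1], 0.5)
  # wtp 1000: NMB = 100*sign... draws: 1 (100+100>0), 2 (-100+100=0, not >0),
  # 3 (100-200<0), 4 (-100-200<0) -> 1/4
  expect_equal(cv$prob_ce[2], 0.25)
  # wtp 5000: draws 1 (600), 2 (-400), 3 (300), 4 (-700) -> 1/2
  expect_equal(cv$prob_ce[3], 0.5)
  # wtp -> infinity: fraction with positive incremental effect
  expect_equal(cv$prob_ce[4], mean(hand$draws$delta_qaly > 0))
  expect_true(all(cv$prob_ce >= 0 & cv$prob_ce <= 1))

  all_dom <- structure(list(draws = data.frame(
    draw = 1:3, delta_cost = c(-1, -2, -3), delta_qaly = c(0.1, 0.2, 0.3)
  )), class = "psa_draws")
  expect_equal(ceac(all_dom, c(0, 2e4))$prob_ce, c(1, 1))

  expect_error(ceac(hand, numeric(0)), "non-empty")
  expect_error(ceac(hand, c(2, 1)), "increasing")
})

test_that("tornado covers the census, sorts by width, and is linear in costs", {
  b <- default_bundle(horizon_years = 5)   # shorter horizon keeps 80 runs quick
  tn <- tornado(b)
  expect_equal(nrow(tn), nrow(param_table(b)))
  expect_true(all(diff(tn$width) <= 1e-12))
  expect_true(any(tn$clipped[tn$parameter %in%
                               paste0("utility_", alive_states())]))

  # per-cycle accrual is linear in any single state cost: symmetric bar
  base_out <- attr(tn, "base_outcome")
  row <- tn[tn$parameter == "cost_STANDARD_RH1", ]
  expect_equal(abs(row$outcome_high - base_out),
               abs(base_out - row$outcome_low), tolerance = 1e-9)
  # and it only moves that arm's cost
  b_hi <- set_param(b, "cost_STANDARD_RH1", 548 * 1.2)
  expect_equal(arm_totals(run_cohort("BNP", b_hi))$cost,
               arm_totals(run_cohort("BNP", b))$cost)

  # a cost of a state never occupied spans a zero-width bar
  b0 <- b
  b0$transitions[c("p_hosp_nrh", "p_hosp_rh1", "p_hosp_rh2")] <- 0
  tn0 <- tornado(b0)
  rh_costs <- grepl("^cost_.*_RH", tn0$parameter)
  expect_true(all(tn0$width[rh_costs] < 1e-9))
})

test_that("percentile bootstrap behaves on degenerate and seeded input", {
  const <- rep(7.5, 50)
  ci <- bootstrap_ci(const, n_reps = 200, seed = 4)
  expect_equal(ci$low, 7.5)
  expect_equal(ci$high, 7.5)
  expect_equal(ci$point, 7.5)

  set.seed(8)
  x <- rnorm(100)
  a <- bootstrap_ci(x, n_reps = 500, seed = 21)
  b <- bootstrap_ci(x, n_reps = 500, seed = 21)
  expect_identical(a, b)
  expect_lt(a$low, a$point)
  expect_gt(a$high, a$point)
  expect_equal(a$point, mean(x))
  expect_error(bootstrap_ci(1), "at least 2")
})
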