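# Oracle values in this file are frozen from direct high-precision
# arithmetic on the closed forms (computed independently of the engine).

test_that("annual-to-monthly probability conversion is exact and monotone", {
  expect_equal(annual_prob_to_monthly(0), 0)
  expect_equal(annual_prob_to_monthly(1), 1)
  expect_equal(annual_prob_to_monthly(0.218), 0.0202831832119625,
               tolerance = 1e-12)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(annual_prob_to_monthly(p)) > 0))
  expect_true(all(annual_prob_to_monthly(p) >= 0 &
                  annual_prob_to_monthly(p) <= 1))
  expect_error(annual_prob_to_monthly(1.1), "\\[0,1\\]")
})

test_that("background mortality lookup respects band edges", {
  mt <- default_bundle()$mortality
  expect_equal(background_mortality(47, mt), 0.002)
  expect_equal(background_mortality(85, mt), 0.218)
  expect_equal(background_mortality(97, mt), 0.218)
  expect_equal(background_mortality(64.99, mt), 0.0095)
  expect_equal(background_mortality(65, mt), 0.0185)
  expect_error(background_mortality(40, mt), "below")
})

test_that("relative risk scales hospitalisation but never breaks the row", {
  expect_equal(apply_relative_risk(0.168, 1.0, 0.067), 0.168)
  expect_equal(apply_relative_risk(0.168, 0.81, 0.067), 0.13608)
  expect_equal(apply_relative_risk(0.9, 2.0, 0.3), 0.7)
})

test_that("death risks combine as independent competing risks", {
  expect_equal(combine_death(0, 0), 0)
  expect_equal(combine_death(0.067, 0), 0.067)
  expect_equal(combine_death(0.067, 0.0202831832119625), 0.085924209936761,
               tolerance = 1e-12)
  expect_equal(combine_death(0.3, 0.2), combine_death(0.2, 0.3))
  expect_true(combine_death(0.3, 0.2) >= 0.3)
})

test_that("transition matrices have the ladder structure and exact rows", {
  b <- default_bundle()
  for (arm in arms()) {
    M <- build_transition_matrix(arm, 72, b)
    expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(M["DEAD", ]), c(0, 0, 0, 0, 1))
    # no backward or skipping transitions
    expect_equal(M["RH1", "NRH"], 0)
    expect_equal(M["NRH", "RH2"], 0)
    expect_equal(M["RH3", "RH2"], 0)
  }
  # STANDARD NRH row at the 45-49 band, against direct arithmetic:
  # bg = 1-(1-0.002)^(1/12); death = 1-(1-0.067)(1-bg); stay = 1-0.168-death
  M <- build_transition_matrix("STANDARD", 47, b)
  expect_equal(unname(M["NRH", ]),
               c(0.764844357275931, 0.168, 0, 0, 0.0671556427240692),
               tolerance = 1e-12)
  # BNP hospitalisation entries are rr x STANDARD's; death entries equal
  Mb <- build_transition_matrix("BNP", 47, b)
  for (s in c("NRH", "RH1", "RH2")) {
    nxt <- c(NRH = "RH1", RH1 = "RH2", RH2 = "RH3")[[s]]
    expect_equal(Mb[s, nxt], 0.81 * M[s, nxt])
    expect_equal(Mb[s, "DEAD"], M[s, "DEAD"])
  }
})

test_that("literal-stay labelling reads tabulated values as stay probabilities", {
  b <- default_bundle()
  b$config$transition_label_mode <- "literal-stay"
  M <- build_transition_matrix("STANDARD", 47, b)
  expect_equal(M["NRH", "NRH"], 0.168)
  expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
  # stay + death > 1 leaves a negative move residual -> error names the state
  b$transitions[["p_hosp_nrh"]] <- 0.95   # read as stay probability here
  expect_error(build_transition_matrix("STANDARD", 47, b), "NRH")
})

test_that("a fully healthy discounted-free year accrues exactly one QALY", {
  b <- plain_bundle(horizon_years = 1)
  b$transitions[c("p_death_nrh", "p_death_rh1",
                  "p_death_rh2", "p_death_rh3")] <- 0
  tr <- run_cohort("STANDARD", b)
  expect_equal(nrow(tr), 12)
  expect_equal(arm_totals(tr)$qaly, 1.0)
  expect_equal(arm_totals(tr)$life_years, 1.0)
})

test_that("certain death after one cycle leaves a single month of utility", {
  b <- default_bundle()
  b <- zero_mortality(b)
  b$transitions[c("p_hosp_nrh", "p_hosp_rh1", "p_hosp_rh2")] <- 0
  b$transitions[c("p_death_nrh", "p_death_rh1",
                  "p_death_rh2", "p_death_rh3")] <- 1
  tr <- run_cohort("STANDARD", b)
  expect_equal(arm_totals(tr)$qaly, 0.85 / 12)
  expect_equal(nrow(tr), 1)   # the cohort is extinct after the first cycle
})

test_that("occupancy is conserved, death absorbs, zero discounting matches", {
  set.seed(42)
  for (i in 1:8) {
    b <- random_bundle()
    expect_equal(nrow(validate_bundle(b)), 0)
    arm <- sample(arms(), 1)
    tr <- run_cohort(arm, b)
    occ <- rowSums(tr[, health_states()])
    expect_true(all(abs(occ - 1) < 1e-9))
    expect_true(all(diff(tr$DEAD) >= -1e-12))
    expect_true(all(diff(1 - tr$DEAD) <= 1e-12))
    expect_true(all(diff(cumsum(tr$disc_cost)) >= 0))
  }
  b <- random_bundle()
  b$discount$rate_cost <- 0
  b$discount$rate_effect <- 0
  tr <- run_cohort("BNP", b)
  expect_equal(sum(tr$disc_cost), sum(tr$cost))
  expect_equal(sum(tr$disc_qaly), sum(tr$qaly))
})

test_that("neutral relative risk with equal costs makes the arms identical", {
  b <- default_bundle()
  b$effect$rr_hosp <- 1
  b$costs$STANDARD <- b$costs$BNP
  tr_b <- run_cohort("BNP", b)
  tr_s <- run_cohort("STANDARD", b)
  expect_identical(tr_b$disc_cost, tr_s$disc_cost)
  expect_identical(tr_b$disc_qaly, tr_s$disc_qaly)
})

test_that("costs respond monotonically; higher rr weakly lowers BNP QALYs", {
  b <- default_bundle()
  base_cost <- arm_totals(run_cohort("BNP", b))$cost
  b2 <- set_param(b, "cost_BNP_RH2", b$costs$BNP[["RH2"]] * 1.5)
  expect_gt(arm_totals(run_cohort("BNP", b2))$cost, base_cost)
  expect_equal(arm_totals(run_cohort("STANDARD", b2))$cost,
               arm_totals(run_cohort("STANDARD", b))$cost)

  qalys <- vapply(c(0.6, 0.81, 1.0), function(rr) {
    bb <- b
    bb$effect$rr_hosp <- rr
    arm_totals(run_cohort("BNP", bb))$qaly
  }, numeric(1))
  expect_true(all(diff(qalys) <= 1e-12))
})

test_that("two-state reduction matches the geometric-series closed form", {
  p <- 0.05
  b <- plain_bundle()
  b$transitions[c("p_hosp_nrh", "p_hosp_rh1", "p_hosp_rh2")] <- 0
  b$transitions[["p_death_nrh"]] <- p
  tr <- run_cohort("STANDARD", b)
  n <- nrow(tr)
  expect_equal(arm_totals(tr)$life_years,
               (1 - (1 - p)^n) / p / 12, tolerance = 1e-9)
})

test_that("microsimulation matches the trace exactly on degenerate chains", {
  b <- plain_bundle(horizon_years = 2)
  b$transitions[c("p_hosp_nrh", "p_hosp_rh1", "p_hosp_rh2")] <- c(1, 1, 1)
  b$transitions[c("p_death_nrh", "p_death_rh1", "p_death_rh2")] <- 0
  b$transitions[["p_death_rh3"]] <- 1
  b$discount$rate_cost <- 0.058
  b$utilities[] <- c(0.9, 0.8, 0.7, 0.6)
  ms <- microsim_oracle("STANDARD", b, 50, seed = 7)
  ct <- arm_totals(run_cohort("STANDARD", b))
  expect_equal(ms$cost, ct$cost, tolerance = 1e-12)
  expect_equal(ms$qaly, ct$qaly, tolerance = 1e-12)
  expect_equal(ms$life_years, ct$life_years, tolerance = 1e-12)

  ms2 <- microsim_oracle("STANDARD", b, 50, seed = 7)
  expect_identical(ms, ms2)
})

test_that("event cost semantics charge rehospitalisation states on entry", {
  b <- plain_bundle(horizon_years = 1)
  b$transitions[c("p_hosp_nrh", "p_hosp_rh1", "p_hosp_rh2")] <- c(1, 0, 0)
  b$transitions[c("p_death_nrh", "p_death_rh1",
                  "p_death_rh2", "p_death_rh3")] <- 0
  b$costs$STANDARD[] <- c(10, 500, 0, 0)
  b$config$cost_semantics <- "event"
  tr <- run_cohort("STANDARD", b)
  # one cycle in NRH (10) + one admission into RH1 (500), then RH1 occupancy
  # is free of further charges
  expect_equal(arm_totals(tr)$cost, 10 + 500)
  ms <- microsim_oracle("STANDARD", b, 20, seed = 1)
  expect_equal(ms$cost, 510, tolerance = 1e-12)

  b$config$cost_semantics <- "per-cycle"
  expect_equal(arm_totals(run_cohort("STANDARD", b))$cost, 10 + 11 * 500)
})

test_that("half-cycle correction averages start and end occupancy", {
  b <- plain_bundle(horizon_years = 1)
  b$transitions[c("p_hosp_nrh", "p_hosp_rh1", "p_hosp_rh2")] <- 0
  b$transitions[["p_death_nrh"]] <- 0.5
  b$config$half_cycle_correction <- TRUE
  tr <- run_cohort("STANDARD", b)
  # first-cycle alive fraction averages (1 + 0.5)/2
  expect_equal(tr$qaly[1], 0.75 / 12)
  occ <- rowSums(tr[, health_states()])
  expect_true(all(abs(occ - 1) < 1e-9))
})
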