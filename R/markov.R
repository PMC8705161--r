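# Monthly-cycle cohort engine: transition matrices per arm and age band,
# deterministic cohort trace with discounted cost/QALY accrual, and an
# individual-level microsimulation used as a validation oracle.

#' Convert an annual probability to a monthly probability
#'
#' Uses the constant-rate transformation `1 - (1 - p)^(1/12)`, the standard
#' choice when a per-cycle probability must be derived from an annual one.
#'
#' @param p_annual Annual probability in \[0, 1\] (vectorised).
#' @return Monthly probability in \[0, 1\].
#' @export
annual_prob_to_monthly <- function(p_annual) {
  if (any(!is.finite(p_annual) | p_annual < 0 | p_annual > 1)) {
    stop("annual probability must be in [0,1]")
  }
  1 - (1 - p_annual)^(1 / 12)
}

#' Look up annual background mortality for an age
#'
#' Returns the all-cause annual death probability of the age band containing
#' `age`; ages of 85 and above use the open-ended top band. Band upper bounds
#' are inclusive (age 64.99 still belongs to the 60--64 band).
#'
#' @param age Age in years (vectorised), at least the lowest band start (45).
#' @param table Mortality table (`data.frame` with `age_lo`, `age_hi`,
#'   `annual_prob`), e.g. `default_bundle()$mortality`.
#' @return Annual death probability.
#' @export
background_mortality <- function(age, table) {
  if (any(age < min(table$age_lo))) {
    stop(sprintf("age below mortality table domain (first band starts at %g)",
                 min(table$age_lo)))
  }
  idx <- findInterval(age, table$age_lo)
  table$annual_prob[idx]
}

#' Apply the hospitalisation relative risk, preserving row feasibility
#'
#' Multiplies the monthly hospitalisation probability by the relative risk
#' and caps the result so the state's transition row stays feasible
#' (hospitalisation + death cannot exceed 1).
#'
#' @param p_hosp Monthly hospitalisation probability.
#' @param rr Relative risk (dimensionless, > 0).
#' @param p_death_row Monthly death probability already occupying the row.
#' @return Adjusted monthly hospitalisation probability.
#' @export
apply_relative_risk <- function(p_hosp, rr, p_death_row) {
  pmin(rr * p_hosp, 1 - p_death_row)
}

#' Combine disease-specific and background death as independent risks
#'
#' Competing-risk combination: `1 - (1 - p_hf)(1 - p_bg)`. Symmetric and
#' never below either input.
#'
#' @param p_hf_death Monthly heart-failure death probability.
#' @param p_bg_death Monthly background (all-cause) death probability.
#' @return Combined monthly death probability.
#' @export
combine_death <- function(p_hf_death, p_bg_death) {
  if (any(p_hf_death < 0 | p_hf_death > 1 | p_bg_death < 0 | p_bg_death > 1)) {
    stop("death probabilities must be in [0,1]")
  }
  1 - (1 - p_hf_death) * (1 - p_bg_death)
}

#' Build the 5x5 monthly transition matrix for an arm at an age
#'
#' For each alive state the death entry combines the state's heart-failure
#' death probability with age-banded background mortality (converted to
#' monthly); the hospitalisation entry moves the patient one
#' rehospitalisation state up (relative-risk-adjusted in the BNP arm); the
#' diagonal takes the residual. RH3 has no upward transition (further
#' re-admissions collapse into RH3) and DEAD is absorbing.
#'
#' Under `transition_label_mode = "literal-stay"` the tabulated per-state
#' probabilities are read as stay probabilities instead, with the move
#' probability taken as the residual; the relative risk then scales that
#' residual move probability.
#'
#' @param arm `"BNP"` or `"STANDARD"`.
#' @param age Age in years.
#' @param bundle A valid `param_bundle`.
#' @return A 5x5 matrix with `dimnames` the health states and attributes
#'   `arm` and `age`.
#' @export
build_transition_matrix <- function(arm, age, bundle) {
  arm <- match.arg(arm, arms())
  tr <- bundle$transitions
  p_bg <- annual_prob_to_monthly(background_mortality(age, bundle$mortality))
  mode <- bundle$config$transition_label_mode

  p_death <- c(NRH = combine_death(tr[["p_death_nrh"]], p_bg),
               RH1 = combine_death(tr[["p_death_rh1"]], p_bg),
               RH2 = combine_death(tr[["p_death_rh2"]], p_bg),
               RH3 = combine_death(tr[["p_death_rh3"]], p_bg))
  printed_hosp <- c(NRH = tr[["p_hosp_nrh"]], RH1 = tr[["p_hosp_rh1"]],
                    RH2 = tr[["p_hosp_rh2"]], RH3 = 0)
  if (mode == "next-state") {
    p_hosp <- printed_hosp
  } else {
    # literal-stay: printed value is the stay probability; the move
    # probability is what is left after staying and dying
    p_hosp <- c(NRH = 1 - printed_hosp[["NRH"]] - p_death[["NRH"]],
                RH1 = 1 - printed_hosp[["RH1"]] - p_death[["RH1"]],
                RH2 = 1 - printed_hosp[["RH2"]] - p_death[["RH2"]],
                RH3 = 0)
    if (any(p_hosp < -1e-12)) {
      bad <- names(p_hosp)[p_hosp < -1e-12]
      stop("literal-stay residual negative for state(s): ",
           paste(bad, collapse = ", "))
    }
    p_hosp <- pmax(p_hosp, 0)
  }
  if (arm == "BNP") {
    rr <- bundle$effect$rr_hosp
    p_hosp[c("NRH", "RH1", "RH2")] <- apply_relative_risk(
      p_hosp[c("NRH", "RH1", "RH2")], rr, p_death[c("NRH", "RH1", "RH2")])
  }

  st <- health_states()
  M <- matrix(0, 5, 5, dimnames = list(st, st))
  nxt <- c(NRH = "RH1", RH1 = "RH2", RH2 = "RH3")
  for (s in alive_states()) {
    M[s, "DEAD"] <- p_death[[s]]
    if (s != "RH3") M[s, nxt[[s]]] <- p_hosp[[s]]
    M[s, s] <- 1 - p_death[[s]] - if (s != "RH3") p_hosp[[s]] else 0
    if (M[s, s] < -1e-12) {
      stop(sprintf("infeasible transition row for state %s (residual %.4g)",
                   s, M[s, s]))
    }
    M[s, s] <- max(M[s, s], 0)
  }
  M["DEAD", "DEAD"] <- 1
  attr(M, "arm") <- arm
  attr(M, "age") <- age
  M
}

# Number of monthly cycles implied by the configuration: a fixed horizon if
# set, otherwise until max_age.
n_cycles <- function(bundle) {
  cfg <- bundle$config
  if (!is.null(cfg$horizon_years)) {
    round(cfg$horizon_years * 12)
  } else {
    round((cfg$max_age - cfg$start_age) * 12)
  }
}

# Transition matrices cached per mortality band for one arm.
band_matrices <- function(arm, bundle) {
  cfg <- bundle$config
  bands <- findInterval(cfg$start_age + (seq_len(n_cycles(bundle)) - 1) / 12,
                        bundle$mortality$age_lo)
  mats <- lapply(sort(unique(bands)), function(b) {
    build_transition_matrix(arm, bundle$mortality$age_lo[b], bundle)
  })
  names(mats) <- as.character(sort(unique(bands)))
  list(bands = bands, mats = mats)
}

#' Run the deterministic cohort model for one arm
#'
#' Propagates the cohort occupancy vector from full occupancy of the
#' no-rehospitalisation state through monthly transition matrices (rebuilt
#' whenever the cohort crosses a mortality age band) and accrues per-cycle
#' discounted cost and QALY increments. Discount factors are
#' `(1 + r)^(-t/12)` at cycle `t`; utilities accrue at `1/12` of the annual
#' weight per monthly cycle. The run stops at the configured horizon, at
#' `max_age`, or once the alive fraction falls below `1e-8`.
#'
#' Cost accrual follows `config$cost_semantics`: `"per-cycle"` charges each
#' state's cost for every cycle of occupancy; `"event"` charges a
#' rehospitalisation state's cost once on entry, with the NRH cost still
#' accruing per cycle. With `half_cycle_correction = TRUE` accruals use the
#' average of start- and end-of-cycle occupancy.
#'
#' @param arm `"BNP"` or `"STANDARD"`.
#' @param bundle A valid `param_bundle`.
#' @return A data frame of class `"cohort_trace"`: one row per cycle with
#'   occupancy fractions, age, and (un)discounted cost and QALY increments
#'   per patient. Attributes `arm` and `totals` (see [arm_totals()]).
#' @export
run_cohort <- function(arm, bundle) {
  arm <- match.arg(arm, arms())
  stop_if_invalid(bundle)
  cfg <- bundle$config
  nmax <- n_cycles(bundle)
  bm <- band_matrices(arm, bundle)

  costs <- bundle$costs[[arm]][alive_states()]
  utils_y <- bundle$utilities[alive_states()]
  r_c <- bundle$discount$rate_cost
  r_e <- bundle$discount$rate_effect
  hcc <- isTRUE(cfg$half_cycle_correction)
  event_mode <- cfg$cost_semantics == "event"

  occ <- c(1, 0, 0, 0, 0)
  arrivals <- c(0, 0, 0)   # event mode: new entrants to RH1..RH3 this cycle
  rows <- vector("list", nmax)
  for (t in seq_len(nmax) - 1L) {
    M <- bm$mats[[as.character(bm$bands[t + 1L])]]
    occ_next <- as.numeric(occ %*% M)
    occ_eff <- if (hcc) (occ + occ_next) / 2 else occ
    alive <- occ_eff[1:4]
    df_c <- (1 + r_c)^(-t / 12)
    df_e <- (1 + r_e)^(-t / 12)
    if (event_mode) {
      cost_t <- occ_eff[1] * costs[["NRH"]] +
        sum(arrivals * costs[c("RH1", "RH2", "RH3")])
      # entrants during this cycle arrive (and are charged) next cycle
      arrivals <- vapply(2:4, function(j) sum(occ[-j] * M[-j, j]), numeric(1))
    } else {
      cost_t <- sum(alive * costs)
    }
    qaly_t <- sum(alive * utils_y) / 12
    rows[[t + 1L]] <- c(cycle = t, age = cfg$start_age + t / 12,
                        occ, cost = cost_t, disc_cost = cost_t * df_c,
                        qaly = qaly_t, disc_qaly = qaly_t * df_e)
    occ <- occ_next
    if (sum(occ[1:4]) < 1e-8) {
      rows <- rows[seq_len(t + 1L)]
      break
    }
  }
  trace <- as.data.frame(do.call(rbind, rows))
  names(trace) <- c("cycle", "age", health_states(),
                    "cost", "disc_cost", "qaly", "disc_qaly")
  class(trace) <- c("cohort_trace", "data.frame")
  attr(trace, "arm") <- arm
  attr(trace, "totals") <- list(
    cost = sum(trace$disc_cost),
    qaly = sum(trace$disc_qaly),
    life_years = sum(rowSums(trace[, alive_states()])) / 12,
    cycles = nrow(trace)
  )
  trace
}

#' Per-arm totals of a cohort trace
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @return List with `cost` (discounted USD/patient), `qaly` (discounted),
#'   `life_years` (undiscounted), `cycles`.
#' @export
arm_totals <- function(trace) attr(trace, "totals")

#' Export a cohort trace as tidy CSV
#'
#' One row per (cycle, state) with occupancy and the cycle's discounted
#' increments.
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  long <- do.call(rbind, lapply(health_states(), function(s) {
    data.frame(cycle = trace$cycle, age = trace$age, state = s,
               occupancy = trace[[s]], disc_cost = trace$disc_cost,
               disc_qaly = trace$disc_qaly)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_individuals` patients one by one through the same per-band
#' transition matrices as [run_cohort()], discounting each individual's
#' accruals identically, and returns mean totals with their standard errors.
#' Used to validate the deterministic cohort trace: at large `n` the two
#' must agree within Monte-Carlo error.
#'
#' @param arm `"BNP"` or `"STANDARD"`.
#' @param bundle A valid `param_bundle`.
#' @param n_individuals Number of simulated patients.
#' @param seed Integer seed; same seed gives identical output.
#' @return List with `cost`, `qaly`, `life_years` (means per patient),
#'   `se_cost`, `se_qaly`, `n`.
#' @export
microsim_oracle <- function(arm, bundle, n_individuals, seed) {
  arm <- match.arg(arm, arms())
  stopifnot(n_individuals >= 1)
  stop_if_invalid(bundle)
  set.seed(seed)
  cfg <- bundle$config
  nmax <- n_cycles(bundle)
  bm <- band_matrices(arm, bundle)
  costs <- c(bundle$costs[[arm]][alive_states()], DEAD = 0)
  utils_y <- c(bundle$utilities[alive_states()], DEAD = 0)
  r_c <- bundle$discount$rate_cost
  r_e <- bundle$discount$rate_effect
  event_mode <- cfg$cost_semantics == "event"

  state <- rep.int(1L, n_individuals)   # 1 = NRH ... 5 = DEAD
  cost_i <- numeric(n_individuals)
  qaly_i <- numeric(n_individuals)
  ly_i <- numeric(n_individuals)
  for (t in seq_len(nmax) - 1L) {
    alive <- which(state != 5L)
    if (!length(alive)) break
    M <- bm$mats[[as.character(bm$bands[t + 1L])]]
    df_c <- (1 + r_c)^(-t / 12)
    df_e <- (1 + r_e)^(-t / 12)
    if (!event_mode) {
      cost_i[alive] <- cost_i[alive] + costs[state[alive]] * df_c
    } else {
      in_nrh <- alive[state[alive] == 1L]
      cost_i[in_nrh] <- cost_i[in_nrh] + costs[1L] * df_c
    }
    qaly_i[alive] <- qaly_i[alive] + utils_y[state[alive]] / 12 * df_e
    ly_i[alive] <- ly_i[alive] + 1 / 12
    new_state <- state
    for (s in 1:4) {
      idx <- alive[state[alive] == s]
      if (!length(idx)) next
      new_state[idx] <- sample.int(5L, length(idx), replace = TRUE,
                                   prob = M[s, ])
    }
    if (event_mode && t + 1L < nmax) {
      # charge RH-state cost on entry, discounted at the arrival cycle
      entered <- which(new_state != state & new_state %in% 2:4)
      if (length(entered)) {
        df_next <- (1 + r_c)^(-(t + 1) / 12)
        cost_i[entered] <- cost_i[entered] + costs[new_state[entered]] * df_next
      }
    }
    state <- new_state
  }
  list(cost = mean(cost_i), qaly = mean(qaly_i), life_years = mean(ly_i),
       se_cost = stats::sd(cost_i) / sqrt(n_individuals),
       se_qaly = stats::sd(qaly_i) / sqrt(n_individuals),
       n = n_individuals)
}
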