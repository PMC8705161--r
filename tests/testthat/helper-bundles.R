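# Fixture bundles built in code.

# Mortality table with zero background mortality (same band layout).
zero_mortality <- function(b) {
  b$mortality$annual_prob <- rep(0, nrow(b$mortality))
  b
}

# A clean, fully controllable bundle: no background mortality, no
# discounting, utilities 1, equal unit costs across arms.
plain_bundle <- function(...) {
  b <- default_bundle(...)
  b <- zero_mortality(b)
  b$discount$rate_cost <- 0
  b$discount$rate_effect <- 0
  b$utilities[] <- 1
  b$costs$BNP[] <- 100
  b$costs$STANDARD[] <- 100
  b
}

# Random valid bundle for property tests: transition rows kept feasible
# with headroom for background mortality.
random_bundle <- function() {
  b <- default_bundle()
  for (st in c("nrh", "rh1", "rh2")) {
    d <- runif(1, 0, 0.45)
    h <- runif(1, 0, 0.45)
    b$transitions[[paste0("p_death_", st)]] <- d
    b$transitions[[paste0("p_hosp_", st)]] <- h
  }
  b$transitions[["p_death_rh3"]] <- runif(1, 0, 0.9)
  b$effect$rr_hosp <- runif(1, 0.3, 1.5)
  for (a in arms()) b$costs[[a]][] <- runif(4, 0, 2000)
  b$utilities[] <- runif(4, 0.2, 1)
  b$discount$rate_cost <- runif(1, 0, 0.1)
  b$discount$rate_effect <- runif(1, 0, 0.1)
  b
}
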