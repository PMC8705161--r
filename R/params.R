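# Model inputs: health-state structure, transition probabilities, costs,
# utilities, background mortality, discounting, and run configuration,
# bundled into a single validated object.

#' Health states of the cohort model
#'
#' The model distinguishes outpatients by their number of previous
#' heart-failure rehospitalisations: none (NRH), one to three (RH1--RH3),
#' plus an absorbing dead state. Re-admissions past the third collapse into
#' RH3.
#'
#' @return Character vector of the five state labels, in model order.
#' @export
health_states <- function() c("NRH", "RH1", "RH2", "RH3", "DEAD")

#' Alive (non-absorbing) states
#' @return Character vector of the four alive state labels.
#' @export
alive_states <- function() c("NRH", "RH1", "RH2", "RH3")

#' Treatment arms
#'
#' `"BNP"` is monthly B-type natriuretic peptide guided care; `"STANDARD"`
#' is standard clinical assessment (history and physical examination).
#'
#' @return Character vector of the two arm labels.
#' @export
arms <- function() c("BNP", "STANDARD")

#' Default parameter bundle
#'
#' Returns the complete set of model inputs used in the base-case analysis:
#' monthly transition probabilities (hospitalisation and heart-failure death
#' per state), the relative risk of hospitalisation under BNP-guided care,
#' per-state monthly costs per arm (2019 USD), per-state utility weights,
#' the Iranian age-banded all-cause mortality table, annual discount rates
#' (5.8% costs, 3% effects), and the run configuration.
#'
#' @param ... Named configuration overrides applied to `$config`
#'   (e.g. `start_age = 50`, `horizon_years = 10`).
#' @return A list of class `"param_bundle"` with components `transitions`,
#'   `transition_sds`, `effect`, `costs`, `cost_sds`, `utilities`,
#'   `utility_sds`, `mortality`, `discount`, `config`.
#' @examples
#' b <- default_bundle()
#' b$transitions[["p_hosp_nrh"]]
#' b$costs$BNP[["NRH"]]
#' @export
default_bundle <- function(...) {
  bundle <- structure(list(
    transitions = c(
      p_hosp_nrh  = 0.168,
      p_death_nrh = 0.067,
      p_hosp_rh1  = 0.213,
      p_death_rh1 = 0.075,
      p_hosp_rh2  = 0.268,
      p_death_rh2 = 0.085,
      p_death_rh3 = 0.095
    ),
    transition_sds = c(
      p_hosp_nrh  = 0.37,
      p_death_nrh = 0.24,
      p_hosp_rh1  = 0.36,
      p_death_rh1 = 0.025,
      p_hosp_rh2  = 0.37,
      p_death_rh2 = 0.32,
      p_death_rh3 = 0.33
    ),
    effect = list(rr_hosp = 0.81, rr_log_sd = 0.1),
    costs = list(
      BNP      = c(NRH = 309, RH1 = 446, RH2 = 585, RH3 = 861),
      STANDARD = c(NRH = 272, RH1 = 548, RH2 = 824, RH3 = 1100)
    ),
    cost_sds = list(
      BNP      = c(NRH = 67, RH1 = 100, RH2 = 175, RH3 = 249),
      STANDARD = c(NRH = 65, RH1 = 153, RH2 = 247, RH3 = 341)
    ),
    utilities   = c(NRH = 0.85, RH1 = 0.828, RH2 = 0.809, RH3 = 0.777),
    utility_sds = c(NRH = 0.23, RH1 = 0.25, RH2 = 0.26, RH3 = 0.24),
    mortality = data.frame(
      age_lo = c(45, 50, 55, 60, 65, 70, 75, 80, 85),
      age_hi = c(49, 54, 59, 64, 69, 74, 79, 84, Inf),
      annual_prob = c(0.002, 0.004, 0.0055, 0.0095, 0.0185,
                      0.0355, 0.074, 0.1165, 0.218)
    ),
    discount = list(rate_cost = 0.058, rate_effect = 0.03),
    config = list(
      start_age = 60,
      max_age = 100,
      cycle_length = 1 / 12,       # years; one-month cycles, fixed
      cohort_size = 1000,
      wtp_threshold = 20800,
      psa_draws = 1000,
      bootstrap_reps = 1000,
      seed = 1L,
      transition_label_mode = "next-state",
      cost_semantics = "per-cycle",
      half_cycle_correction = FALSE,
      horizon_years = NULL
    )
  ), class = "param_bundle")
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(bundle$config))
    if (length(unknown)) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    }
    bundle$config[names(overrides)] <- overrides
  }
  bundle
}

#' Parameter census as a flat table
#'
#' One row per uncertain model input: the seven transition probabilities,
#' the hospitalisation relative risk, the eight per-arm state costs, and the
#' four utility weights, with the probability distribution family used for
#' probabilistic sensitivity analysis (Beta for probabilities and utilities,
#' Gamma for costs, log-normal for the relative risk).
#'
#' @param bundle A `param_bundle`.
#' @return A data frame with columns `name`, `value`, `sd`, `distribution`.
#' @export
param_table <- function(bundle) {
  tr <- data.frame(
    name = names(bundle$transitions),
    value = unname(bundle$transitions),
    sd = unname(bundle$transition_sds[names(bundle$transitions)]),
    distribution = "beta"
  )
  rr <- data.frame(
    name = "rr_hosp",
    value = bundle$effect$rr_hosp,
    sd = bundle$effect$rr_log_sd,
    distribution = "lognormal"
  )
  co <- do.call(rbind, lapply(arms(), function(a) {
    data.frame(
      name = paste0("cost_", a, "_", alive_states()),
      value = unname(bundle$costs[[a]]),
      sd = unname(bundle$cost_sds[[a]]),
      distribution = "gamma"
    )
  }))
  ut <- data.frame(
    name = paste0("utility_", alive_states()),
    value = unname(bundle$utilities),
    sd = unname(bundle$utility_sds),
    distribution = "beta"
  )
  out <- rbind(tr, rr, co, ut)
  rownames(out) <- NULL
  out
}

#' Set a single parameter by its census name
#'
#' Names follow [param_table()]: `p_hosp_nrh` ... `p_death_rh3`, `rr_hosp`,
#' `cost_<ARM>_<STATE>`, `utility_<STATE>`.
#'
#' @param bundle A `param_bundle`.
#' @param name Parameter name.
#' @param value New value.
#' @return The modified bundle.
#' @export
set_param <- function(bundle, name, value) {
  if (name %in% names(bundle$transitions)) {
    bundle$transitions[[name]] <- value
  } else if (name == "rr_hosp") {
    bundle$effect$rr_hosp <- value
  } else if (grepl("^cost_", name)) {
    parts <- strsplit(sub("^cost_", "", name), "_")[[1]]
    if (length(parts) != 2 || !parts[1] %in% arms() ||
        !parts[2] %in% alive_states()) {
      stop("unknown parameter: ", name)
    }
    bundle$costs[[parts[1]]][[parts[2]]] <- value
  } else if (grepl("^utility_", name)) {
    st <- sub("^utility_", "", name)
    if (!st %in% alive_states()) stop("unknown parameter: ", name)
    bundle$utilities[[st]] <- value
  } else {
    stop("unknown parameter: ", name)
  }
  bundle
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant: probabilities in \[0, 1\], per-state
#' hospitalisation + heart-failure death probability not exceeding 1,
#' non-negative costs, utilities at most 1, a contiguous mortality table with
#' probabilities non-decreasing in age, non-negative discount rates, and a
#' sane configuration. Violations are returned as data, not thrown.
#'
#' @param bundle A `param_bundle`.
#' @return A data frame with columns `parameter` and `constraint`; zero rows
#'   when the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  v <- list()
  bad <- function(parameter, constraint) {
    v[[length(v) + 1L]] <<- data.frame(parameter = parameter,
                                       constraint = constraint)
  }
  for (nm in names(bundle$transitions)) {
    p <- bundle$transitions[[nm]]
    if (!is.finite(p) || p < 0 || p > 1) bad(nm, "probability must be in [0,1]")
  }
  rows <- list(
    NRH = c("p_hosp_nrh", "p_death_nrh"),
    RH1 = c("p_hosp_rh1", "p_death_rh1"),
    RH2 = c("p_hosp_rh2", "p_death_rh2")
  )
  for (st in names(rows)) {
    s <- sum(bundle$transitions[rows[[st]]])
    if (is.finite(s) && s > 1) {
      bad(paste(rows[[st]], collapse = " + "),
          sprintf("row %s: hospitalisation + HF death must be <= 1", st))
    }
  }
  if (!is.finite(bundle$effect$rr_hosp) || bundle$effect$rr_hosp <= 0) {
    bad("rr_hosp", "relative risk must be > 0")
  }
  for (a in arms()) {
    for (st in alive_states()) {
      if (bundle$costs[[a]][[st]] < 0) {
        bad(paste0("cost_", a, "_", st), "cost must be >= 0")
      }
    }
  }
  for (st in alive_states()) {
    u <- bundle$utilities[[st]]
    if (!is.finite(u) || u > 1) bad(paste0("utility_", st),
                                    "utility must be <= 1")
  }
  mt <- bundle$mortality
  if (any(mt$annual_prob < 0 | mt$annual_prob > 1)) {
    bad("mortality", "annual probabilities must be in [0,1]")
  }
  if (is.unsorted(mt$annual_prob)) {
    bad("mortality", "annual probabilities must be non-decreasing with age")
  }
  if (any(mt$age_lo[-1] != mt$age_hi[-nrow(mt)] + 1)) {
    bad("mortality", "age bands must be contiguous and non-overlapping")
  }
  if (bundle$discount$rate_cost < 0 || bundle$discount$rate_effect < 0) {
    bad("discount", "discount rates must be >= 0")
  }
  cfg <- bundle$config
  if (cfg$start_age < min(mt$age_lo)) {
    bad("start_age", sprintf("start_age must be >= %d", min(mt$age_lo)))
  }
  if (cfg$max_age <= cfg$start_age) bad("max_age", "max_age must exceed start_age")
  if (cfg$cohort_size < 1) bad("cohort_size", "cohort_size must be >= 1")
  if (cfg$wtp_threshold < 0) bad("wtp_threshold", "wtp_threshold must be >= 0")
  if (!cfg$transition_label_mode %in% c("next-state", "literal-stay")) {
    bad("transition_label_mode", "must be 'next-state' or 'literal-stay'")
  }
  if (!cfg$cost_semantics %in% c("per-cycle", "event")) {
    bad("cost_semantics", "must be 'per-cycle' or 'event'")
  }
  if (length(v) == 0) {
    return(data.frame(parameter = character(), constraint = character()))
  }
  do.call(rbind, v)
}

stop_if_invalid <- function(bundle) {
  v <- validate_bundle(bundle)
  if (nrow(v)) {
    stop("invalid parameter bundle: ",
         paste(sprintf("%s (%s)", v$parameter, v$constraint), collapse = "; "))
  }
  invisible(bundle)
}

# Recursively merge a (possibly nested) override list into a bundle section,
# rejecting keys that do not exist in the defaults.
merge_section <- function(base, override, path) {
  unknown <- setdiff(names(override), names(base))
  if (length(unknown)) {
    stop("unknown key(s) in config: ",
         paste(paste0(path, unknown), collapse = ", "))
  }
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && !is.data.frame(base[[nm]])) {
      base[[nm]] <- merge_section(base[[nm]], as.list(override[[nm]]),
                                  paste0(path, nm, "."))
    } else if (is.numeric(base[[nm]]) && length(base[[nm]]) > 1 &&
               !is.null(names(base[[nm]]))) {
      sub <- override[[nm]]
      unknown2 <- setdiff(names(sub), names(base[[nm]]))
      if (length(unknown2)) {
        stop("unknown key(s) in config: ",
             paste(paste0(path, nm, ".", unknown2), collapse = ", "))
      }
      for (k in names(sub)) base[[nm]][[k]] <- sub[[k]]
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a parameter bundle from a YAML configuration file
#'
#' The file holds overrides merged over [default_bundle()]; its sections and
#' keys mirror the bundle structure (`transitions`, `effect`, `costs`,
#' `utilities`, `discount`, `config`, ...). Unknown keys are rejected by
#' name; the resulting bundle must pass [validate_bundle()].
#'
#' @param path Path to a YAML file. An empty file yields the defaults.
#' @return A validated `param_bundle`.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  bundle <- default_bundle()
  if (!is.null(raw) && length(raw)) {
    cls <- class(bundle)
    merged <- merge_section(unclass(bundle), raw, "")
    bundle <- structure(merged, class = cls)
    if (!is.null(raw$mortality)) {
      bundle$mortality <- as.data.frame(raw$mortality)
    }
  }
  stop_if_invalid(bundle)
  bundle
}

#' Write a parameter bundle to YAML
#'
#' Round-trips with [load_bundle()]: loading the written file reproduces the
#' bundle field-by-field.
#'
#' @param bundle A `param_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  x <- unclass(bundle)
  x$transitions <- as.list(x$transitions)
  x$transition_sds <- as.list(x$transition_sds)
  x$costs <- lapply(x$costs, as.list)
  x$cost_sds <- lapply(x$cost_sds, as.list)
  x$utilities <- as.list(x$utilities)
  x$utility_sds <- as.list(x$utility_sds)
  x$mortality <- lapply(as.list(x$mortality), unname)
  x$config <- x$config[!vapply(x$config, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Export / import the parameter census as CSV
#'
#' Columns: `name`, `value`, `sd`, `distribution`, `source`. Import applies
#' the `value` column onto a bundle via [set_param()].
#'
#' @param bundle A `param_bundle`.
#' @param path CSV path.
#' @return `export_params_csv`: `path` invisibly. `import_params_csv`: the
#'   modified bundle.
#' @export
export_params_csv <- function(bundle, path) {
  tab <- param_table(bundle)
  tab$source <- "default bundle"
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_params_csv
#' @export
import_params_csv <- function(bundle, path) {
  tab <- utils::read.csv(path)
  for (i in seq_len(nrow(tab))) {
    bundle <- set_param(bundle, tab$name[i], tab$value[i])
  }
  bundle
}

#' @export
print.param_bundle <- function(x, ...) {
  cat("<param_bundle>\n")
  cat(sprintf("  start age %g, max age %g, one-month cycles, wtp %g USD/QALY\n",
              x$config$start_age, x$config$max_age, x$config$wtp_threshold))
  cat(sprintf("  discounting: costs %.1f%%/y, effects %.1f%%/y\n",
              100 * x$discount$rate_cost, 100 * x$discount$rate_effect))
  cat(sprintf("  %d uncertain parameters (see param_table())\n",
              nrow(param_table(x))))
  invisible(x)
}
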