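# Incremental cost-effectiveness analytics: deltas, ICER with dominance
# classification, net monetary benefit, and subgroup/scenario batch runs.

#' Incremental cost and effect between two strategies
#'
#' Convention: strategy `a` is the intervention (BNP-guided care), `b` the
#' comparator (standard clinical assessment); `delta = a - b`.
#'
#' @param cost_a,qaly_a Intervention totals.
#' @param cost_b,qaly_b Comparator totals.
#' @return Named list with `delta_cost` (USD) and `delta_qaly` (QALYs).
#' @examples
#' incremental(1835, 2.18, 2376, 2.07)  # saving of 541 USD, 0.11 QALYs gained
#' @export
incremental <- function(cost_a, qaly_a, cost_b, qaly_b) {
  list(delta_cost = cost_a - cost_b, delta_qaly = qaly_a - qaly_b)
}

#' Classify an incremental result and compute the ICER
#'
#' Quadrant logic: lower cost and higher effect is *dominant* (the ICER is
#' not a decision quantity); higher cost and lower effect is *dominated*;
#' otherwise the incremental cost-effectiveness ratio
#' `delta_cost / delta_qaly` applies. With zero incremental effect the
#' classification falls back to the sign of the cost difference (`tie` when
#' both are zero). The integer display value truncates toward zero.
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental effect (QALYs).
#' @return List of class `"cea_class"`: `classification` (`"dominant"`,
#'   `"dominated"`, `"icer"`, `"tie"`), `icer` (full precision, `NA` unless
#'   classification is `"icer"`), `icer_display` (truncated toward zero).
#' @examples
#' icer(-541, 0.11)   # dominant
#' icer(140, 0.30)    # 466 USD/QALY on integer display
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    classification <- if (delta_cost < 0) "dominant"
                      else if (delta_cost > 0) "dominated" else "tie"
    value <- NA_real_
  } else if (delta_cost < 0 && delta_qaly > 0) {
    classification <- "dominant"
    value <- NA_real_
  } else if (delta_cost > 0 && delta_qaly < 0) {
    classification <- "dominated"
    value <- NA_real_
  } else {
    classification <- "icer"
    value <- delta_cost / delta_qaly
  }
  structure(list(classification = classification, icer = value,
                 icer_display = if (is.na(value)) NA_real_ else trunc(value)),
            class = "cea_class")
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_qaly - delta_cost`; positive exactly when the
#' intervention is cost-effective at the willingness-to-pay threshold.
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental effect (QALYs).
#' @param wtp Willingness to pay (USD/QALY, >= 0); vectorised.
#' @return NMB in USD.
#' @export
nmb <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * delta_qaly - delta_cost
}

#' Run the full two-arm model and summarise cost-effectiveness
#'
#' Runs [run_cohort()] for both arms under one bundle and assembles per-arm
#' totals, incremental cost and effect (BNP minus standard), dominance
#' classification or ICER, and the net monetary benefit at the configured
#' willingness-to-pay threshold.
#'
#' @param bundle A valid `param_bundle`.
#' @param keep_traces Keep the two cohort traces in the result (default
#'   `FALSE`).
#' @return A list of class `"cea_result"` with `arms` (per-arm totals),
#'   `delta_cost`, `delta_qaly`, `classification`, `icer`, `icer_display`,
#'   `nmb`, `wtp`, and optionally `traces`.
#' @export
run_cea <- function(bundle, keep_traces = FALSE) {
  tr_b <- run_cohort("BNP", bundle)
  tr_s <- run_cohort("STANDARD", bundle)
  tot_b <- arm_totals(tr_b)
  tot_s <- arm_totals(tr_s)
  inc <- incremental(tot_b$cost, tot_b$qaly, tot_s$cost, tot_s$qaly)
  cls <- icer(inc$delta_cost, inc$delta_qaly)
  res <- list(
    arms = list(BNP = tot_b, STANDARD = tot_s),
    delta_cost = inc$delta_cost,
    delta_qaly = inc$delta_qaly,
    classification = cls$classification,
    icer = cls$icer,
    icer_display = cls$icer_display,
    nmb = nmb(inc$delta_cost, inc$delta_qaly, bundle$config$wtp_threshold),
    wtp = bundle$config$wtp_threshold
  )
  if (keep_traces) res$traces <- list(BNP = tr_b, STANDARD = tr_s)
  structure(res, class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> BNP vs standard clinical assessment\n")
  for (a in names(x$arms)) {
    cat(sprintf("  %-9s cost %9.2f USD  qalys %6.4f  (%.2f life-years)\n",
                a, x$arms[[a]]$cost, x$arms[[a]]$qaly,
                x$arms[[a]]$life_years))
  }
  cat(sprintf("  delta cost %.2f USD, delta QALYs %.4f -> %s",
              x$delta_cost, x$delta_qaly, x$classification))
  if (x$classification == "icer") cat(sprintf(" (%.0f USD/QALY)", x$icer))
  cat(sprintf("; NMB %.0f USD at wtp %g\n", x$nmb, x$wtp))
  invisible(x)
}

#' Cost-effectiveness results for patient subgroups
#'
#' Each subgroup spec provides a `label`, a `start_age`, and optional
#' parameter overrides (named list applied via [set_param()]); the two-arm
#' model is run in full per subgroup. With no subgroup-specific inputs the
#' runs differ only through age-driven background mortality.
#'
#' @param bundle A valid `param_bundle`.
#' @param subgroup_specs List of lists: `label`, `start_age`,
#'   optional `overrides`.
#' @return List of subgroup results, each holding `label` and a
#'   `cea_result`.
#' @export
run_subgroups <- function(bundle, subgroup_specs) {
  lapply(subgroup_specs, function(spec) {
    b <- bundle
    b$config$start_age <- spec$start_age
    for (nm in names(spec$overrides)) {
      b <- set_param(b, nm, spec$overrides[[nm]])
    }
    list(label = spec$label, result = run_cea(b))
  })
}

#' Scenario analyses
#'
#' Each scenario spec may override the utility set (named vector over the
#' alive states) and/or the time horizon in years; the base-case bundle is
#' left untouched. Unknown spec keys are rejected.
#'
#' @param bundle A valid `param_bundle`.
#' @param scenario_specs List of lists: `label`, optional `utilities`,
#'   optional `horizon_years`.
#' @return List of scenario results, each holding `label` and a
#'   `cea_result`.
#' @export
run_scenarios <- function(bundle, scenario_specs) {
  lapply(scenario_specs, function(spec) {
    unknown <- setdiff(names(spec), c("label", "utilities", "horizon_years"))
    if (length(unknown)) {
      stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
    }
    b <- bundle
    if (!is.null(spec$utilities)) {
      b$utilities[names(spec$utilities)] <- spec$utilities
    }
    if (!is.null(spec$horizon_years)) b$config$horizon_years <- spec$horizon_years
    list(label = spec$label, result = run_cea(b))
  })
}

#' Flatten CEA results into a table
#'
#' Mirrors the layout of a published cost-effectiveness table: one row per
#' (labelled) result with per-arm cost and QALYs, the increments, and the
#' classification/ICER.
#'
#' @param results A `cea_result`, or a list of `list(label=, result=)` as
#'   returned by [run_subgroups()] / [run_scenarios()].
#' @return A data frame.
#' @export
cea_table <- function(results) {
  if (inherits(results, "cea_result")) {
    results <- list(list(label = "base case", result = results))
  }
  do.call(rbind, lapply(results, function(x) {
    r <- x$result
    data.frame(
      label = x$label,
      cost_bnp = r$arms$BNP$cost, qaly_bnp = r$arms$BNP$qaly,
      cost_standard = r$arms$STANDARD$cost, qaly_standard = r$arms$STANDARD$qaly,
      delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
      classification = r$classification,
      icer = r$icer, nmb = r$nmb
    )
  }))
}
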