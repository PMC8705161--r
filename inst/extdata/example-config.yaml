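# Example override file for load_bundle(). Any subset of the bundle's
# sections/keys may appear; values merge over the defaults and unknown keys
# are rejected. Sections: transitions, transition_sds, effect, costs,
# cost_sds, utilities, utility_sds, mortality, discount, config.
effect:
  rr_hosp: 0.81
  rr_log_sd: 0.15        # log-scale sd of the RR sampling distribution
discount:
  rate_cost: 0.03        # use a common 3%/y rate for costs too
config:
  start_age: 55
  horizon_years: 10
  cost_semantics: per-cycle
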