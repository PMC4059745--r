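# Shared fixtures: built in code, small enough for fast unit tests.

default_params <- model_parameters()

# a standard starting animal (12-week scale biometrics)
std_init <- function(p = default_params) initial_state(400, 70, p)

# short constant schedule helpers
const_schedule <- function(grams, days) feeding_schedule(rep(grams, days))

# cached noiseless 3-rat ad-libitum cohort used by several estimation tests
noiseless_al <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sch <- with_lead_in(build_AL(56), 5)
      spec <- cohort_spec(n_per_group = 3, cv = 0, weight_noise_sd = 0,
                          intake_noise_sd = 0, seed = 7)
      cache <<- list(cohort = generate_cohort(spec, list(AL = sch)),
                     schedule = sch)
    }
    cache
  }
})

# parameter set with an override vector applied
params_with <- function(overrides, base = default_params) {
  v <- as.numeric(base)
  names(v) <- names(base)
  v[names(overrides)] <- overrides
  do.call(model_parameters, as.list(v))
}
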