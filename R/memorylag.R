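# Memory-lag recovery study: the package's principal self-consistency
# experiment. Synthetic weekly-varying hypocaloric cohorts are generated from
# the reference parameter set and the long memory window is re-estimated by
# the step-3 procedure, seed by seed.

#' Recover the long memory window from synthetic hypocaloric cohorts
#'
#' For each seed: build a weekly-randomised hypocaloric schedule (with the
#' 5-day ad-libitum lead-in), simulate a 6-rat cohort from the reference
#' parameters, add Gaussian noise (sd `weight_noise_sd`) to the weekly body
#' weights, then re-estimate the memory trio with [fit_step3()], seeding the
#' window search from a coarse grid of long-window starts. Terminal fat mass
#' is noise-free in this design, so it enters the objective with a high
#' weight (weighted least squares).
#'
#' @param n_seeds number of independent cohorts.
#' @param base_seed first seed; seeds `base_seed + 0:(n_seeds-1)` are used.
#' @param p generating (and starting) parameter set.
#' @param n_rats rats per cohort.
#' @param weight_noise_sd weekly body-weight noise, g.
#' @param dt integrator step for generation and fitting, minutes.
#' @param tau2_starts long-window starting grid, days.
#' @param fat_weight RSS weight on the terminal fat-mass residual.
#' @param restarts,maxit optimizer controls per start.
#' @return list with `estimates` (data.frame seed, mem_gain, tau1, tau2,
#'   rss), `tau2_mean`, `tau2_median`, `tau2_sd`.
#' @export
memory_lag_study <- function(n_seeds = 10, base_seed = 1,
                             p = model_parameters(), n_rats = 6,
                             weight_noise_sd = 5, dt = 2,
                             tau2_starts = c(4, 8, 12), fat_weight = 25,
                             restarts = 1, maxit = 400) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    seed <- base_seed + i - 1L
    sch <- with_lead_in(build_H1(56, seed = seed), 5)
    spec <- cohort_spec(n_per_group = n_rats, cv = 0,
                        weight_noise_sd = weight_noise_sd,
                        intake_noise_sd = 0, seed = seed)
    coh <- generate_cohort(spec, list(H1 = sch), p, dt = dt)
    f3 <- fit_step3(coh, sch, p, dt = dt,
                    weights = c(bw = 1, fat = fat_weight, intake = 0),
                    restarts = restarts, maxit = maxit, seed = seed,
                    tau2_starts = tau2_starts)
    data.frame(seed = seed, mem_gain = f3$estimates[["mem_gain"]],
               tau1 = f3$estimates[["tau1"]], tau2 = f3$estimates[["tau2"]],
               rss = f3$rss)
  })
  est <- do.call(rbind, rows)
  list(estimates = est, tau2_mean = mean(est$tau2),
       tau2_median = stats::median(est$tau2), tau2_sd = stats::sd(est$tau2))
}
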