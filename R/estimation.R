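# Three-step parameter-estimation pipeline, AIC model comparison and
# rejection-ABC posterior summaries.
#
# Step 1 fits the body-composition subsystem (driven by each rat's measured
# daily intake) to weekly body weight and terminal fat mass of the ad-libitum
# group: partition constants + baseline rate of energy expenditure, per rat,
# then averaged. Step 2 fits the four hunger coefficients on the ad-libitum
# group with consumption equal to hunger (unlimited food). Step 3 fits the
# memory trio (gain, tau1, tau2) on the weekly-varying hypocaloric group with
# everything else fixed. All fits are Nelder-Mead on log-transformed
# parameters with jittered restarts.

#' Residual sum of squares between observed and simulated records
#'
#' Sum over rats and time points of squared differences for weekly body
#' weight, plus squared terminal fat-mass error and squared daily-intake
#' error where those components carry non-zero weight. Units are g^2
#' throughout (unweighted mixing by default).
#'
#' @param observed a cohort (list of rat records).
#' @param simulated a list, one element per rat, each with `weekly_weights`,
#'   `terminal_fat` and `daily_intake` fields as produced by the simulator
#'   observers.
#' @param weights named numeric: `bw`, `fat`, `intake` component weights.
#' @return scalar RSS.
#' @export
rss_records <- function(observed, simulated,
                        weights = c(bw = 1, fat = 1, intake = 0)) {
  if (length(observed) != length(simulated))
    stop("observed and simulated must cover the same rats")
  total <- 0
  for (i in seq_along(observed)) {
    o <- observed[[i]]; s <- simulated[[i]]
    if (weights[["bw"]] > 0) {
      if (!identical(o$weekly_weights$week, s$weekly_weights$week))
        stop("observation weeks do not match simulated weeks for rat ", i)
      total <- total + weights[["bw"]] *
        sum((o$weekly_weights$BW_g - s$weekly_weights$BW_g)^2)
    }
    if (weights[["fat"]] > 0 && !is.null(o$terminal_fat) &&
        !is.na(o$terminal_fat))
      total <- total + weights[["fat"]] * (o$terminal_fat - s$terminal_fat)^2
    if (weights[["intake"]] > 0) {
      if (!identical(o$daily_intake$day, s$daily_intake$day))
        stop("observation days do not match simulated days for rat ", i)
      total <- total + weights[["intake"]] *
        sum((o$daily_intake$consumed_g - s$daily_intake$consumed_g)^2)
    }
  }
  total
}

#' Akaike information criterion for a least-squares fit
#'
#' `AIC = n log(RSS / n) + 2 k` with `n` the number of points used to
#' evaluate the results, `RSS` the residual sum of squares and `k` the number
#' of estimated parameters. A zero RSS returns `-Inf` (perfect-fit sentinel).
#'
#' @param rss residual sum of squares.
#' @param n_points number of residual points.
#' @param n_params number of estimated parameters.
#' @return scalar AIC.
#' @export
aic <- function(rss, n_points, n_params) {
  stopifnot(n_points > n_params, n_params >= 0, rss >= 0)
  if (rss == 0) return(-Inf)
  n_points * log(rss / n_points) + 2 * n_params
}

# Nelder-Mead on log-parameters with jittered restarts; returns the best run.
nm_restarts <- function(objective, start, restarts = 5, jitter_sd = 0.08,
                        seed = 1, maxit = 600, reltol = 1e-8) {
  lstart <- log(start)
  jit <- withr_seed(seed, matrix(rnorm(restarts * length(start), 0, jitter_sd),
                                 nrow = restarts))
  jit[1, ] <- 0 # first run starts exactly at `start`
  best <- NULL
  total_evals <- 0L
  for (r in seq_len(restarts)) {
    fit <- optim(lstart + jit[r, ], function(lp) objective(exp(lp)),
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
    total_evals <- total_evals + fit$counts[["function"]]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(par = setNames(exp(best$par), names(start)), value = best$value,
       iterations = total_evals, converged = best$convergence == 0)
}

fit_result <- function(step, estimates, rss, n_points, n_params, iterations,
                       converged, per_rat = NULL) {
  structure(list(step = step, estimates = estimates, rss = rss,
                 n_points = n_points, n_params = n_params,
                 aic = aic(rss, n_points, n_params),
                 iterations = iterations, converged = converged,
                 per_rat = per_rat),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s): RSS = %.4g over %d points, %d parameters, AIC = %.2f%s\n",
              x$step, x$rss, x$n_points, x$n_params, x$aic,
              if (x$converged) "" else " [not converged]"))
  print(x$estimates)
  invisible(x)
}

# simulate the driven body-composition subsystem for one rat and extract the
# weekly body weights + terminal fat on the rat's observation grid
step1_predict <- function(rec, pvec, lambda, energy_density, lead_in_days,
                          dt) {
  q_daily <- rec$daily_intake$consumed_g * energy_density
  out <- .sim_bodycomp_cpp(rec$F0, rec$BW0 - rec$F0, pvec, lambda, q_daily,
                           dt)
  weeks <- rec$weekly_weights$week
  idx <- lead_in_days + weeks * 7 + 1 # +1: row 1 is day 0
  list(weekly_weights = data.frame(week = weeks,
                                   BW_g = out[idx, 1] + out[idx, 2]),
       terminal_fat = out[nrow(out), 1])
}

#' Estimation step 1: partition constants and baseline expenditure
#'
#' Fits `part_K`, `part_A`, `part_B`, `part_c` and `lambda0` per rat by
#' driving the two-compartment body-composition subsystem with the rat's
#' measured daily intake and minimizing the RSS of weekly body weight and
#' terminal fat mass; the per-rat estimates are then averaged into one
#' population set.
#'
#' @param al_records ad-libitum cohort records (with measured daily intake).
#' @param p starting parameter set (initial guesses for the fitted subset and
#'   fixed values for everything else).
#' @param energy_density diet energy density, kJ/g.
#' @param lead_in_days ad-libitum lead-in length in the records' schedule.
#' @param dt subsystem integrator step, minutes.
#' @param restarts,maxit Nelder-Mead restarts and per-run iteration cap.
#' @param seed seed for the restart jitter.
#' @return a `fit_result` whose `estimates` are the averaged population
#'   values; `per_rat` holds the individual fits.
#' @export
fit_step1 <- function(al_records, p = model_parameters(),
                      energy_density = 12.6, lead_in_days = 5, dt = 10,
                      restarts = 5, maxit = 600, seed = 1) {
  fitted_names <- c("part_K", "part_A", "part_B", "part_c", "lambda0")
  per_rat <- lapply(seq_along(al_records), function(i) {
    rec <- al_records[[i]]
    obj <- function(theta) {
      pv <- as.numeric(p)
      names(pv) <- names(p)
      pv[fitted_names] <- theta
      pred <- step1_predict(rec, pv[PARAM_NAMES], theta[5], energy_density,
                            lead_in_days, dt)
      sum((rec$weekly_weights$BW_g - pred$weekly_weights$BW_g)^2) +
        (rec$terminal_fat - pred$terminal_fat)^2
    }
    nm_restarts(obj, setNames(as.numeric(p[fitted_names]), fitted_names),
                restarts = restarts, maxit = maxit, seed = seed + i)
  })
  est <- colMeans(do.call(rbind, lapply(per_rat, `[[`, "par")))
  # RSS of the aggregated set over the whole group
  rss <- sum(vapply(seq_along(al_records), function(i) {
    rec <- al_records[[i]]
    pv <- as.numeric(p); names(pv) <- names(p)
    pv[fitted_names] <- est
    pred <- step1_predict(rec, pv[PARAM_NAMES], est[["lambda0"]],
                          energy_density, lead_in_days, dt)
    sum((rec$weekly_weights$BW_g - pred$weekly_weights$BW_g)^2) +
      (rec$terminal_fat - pred$terminal_fat)^2
  }, numeric(1)))
  n_pts <- sum(vapply(al_records,
                      function(r) nrow(r$weekly_weights) + 1L, integer(1)))
  fit_result("step1", est, rss, n_pts, length(fitted_names),
             sum(vapply(per_rat, `[[`, numeric(1), "iterations")),
             all(vapply(per_rat, `[[`, logical(1), "converged")),
             per_rat = per_rat)
}

# simulate the full model for each rat of a cohort under a common schedule
# (or each rat's own group schedule) and extract the observation tables
predict_cohort <- function(records, schedule, p, dt, memory_on = TRUE) {
  lapply(records, function(rec) {
    init <- initial_state(rec$BW0, rec$F0, p)
    tr <- simulate(p, schedule, init, dt = dt, memory_on = memory_on,
                   stride = MINUTES_PER_DAY / dt)
    ww <- observe_weekly_weights(tr)
    di <- observe_daily_intake(tr)
    list(weekly_weights = ww[seq_len(nrow(rec$weekly_weights)), ],
         terminal_fat = tr$final_state[["F"]],
         daily_intake = di[, c("day", "consumed_g")])
  })
}

#' Estimation step 2: hunger coefficients
#'
#' Fits the four hunger coefficients (`hunger_ghrelin`, `hunger_leptin`,
#' `hunger_glucose`, `hunger_relax`) on the ad-libitum group with the step-1
#' parameters fixed and consumption equal to hunger (unlimited food). The
#' objective includes the daily-intake series alongside weekly body weight
#' and terminal fat: weekly weights alone leave the fast hunger dynamics
#' almost unconstrained.
#'
#' @param al_records ad-libitum cohort records.
#' @param p parameter set carrying the step-1 estimates; the four hunger
#'   entries are the starting guesses.
#' @param schedule the ad-libitum schedule the records were observed under.
#' @param dt integrator step, minutes.
#' @param weights RSS component weights (see [rss_records()]).
#' @param restarts,maxit,seed optimizer controls.
#' @return a `fit_result`.
#' @export
fit_step2 <- function(al_records, p, schedule, dt = 2,
                      weights = c(bw = 1, fat = 1, intake = 1),
                      restarts = 3, maxit = 400, seed = 1) {
  fitted_names <- c("hunger_ghrelin", "hunger_leptin", "hunger_glucose",
                    "hunger_relax")
  obj <- function(theta) {
    pv <- as.numeric(p); names(pv) <- names(p)
    pv[fitted_names] <- theta
    p2 <- do.call(model_parameters, as.list(pv))
    sim <- predict_cohort(al_records, schedule, p2, dt)
    rss_records(al_records, sim, weights)
  }
  fit <- nm_restarts(obj, setNames(as.numeric(p[fitted_names]), fitted_names),
                     restarts = restarts, maxit = maxit, seed = seed)
  n_pts <- sum(vapply(al_records, function(r)
    nrow(r$weekly_weights) + 1L +
      (weights[["intake"]] > 0) * nrow(r$daily_intake), integer(1)))
  fit_result("step2", fit$par, fit$value, n_pts, length(fitted_names),
             fit$iterations, fit$converged)
}

# objective over the memory trio (gain k, tau1, tau2) on a cohort observed
# under one shared schedule; parameterized as (log k, log tau1,
# log(tau2 - tau1)) so tau1 < tau2 holds by construction
make_step3_objective <- function(records, schedule, p, dt = 1,
                                 weights = c(bw = 1, fat = 1, intake = 0)) {
  function(k, tau1, tau2) {
    # windows that collapse onto the same step count cannot be simulated;
    # return a large finite penalty so the optimizer backs away
    n1 <- round(tau1 * MINUTES_PER_DAY / dt)
    n2 <- round(tau2 * MINUTES_PER_DAY / dt)
    if (n1 < 1 || n2 <= n1 || tau2 > 56) return(1e12)
    pv <- as.numeric(p); names(pv) <- names(p)
    pv[c("mem_gain", "tau1", "tau2")] <- c(k, tau1, tau2)
    p2 <- do.call(model_parameters, as.list(pv))
    sim <- predict_cohort(records, schedule, p2, dt)
    rss_records(records, sim, weights)
  }
}

#' Estimation step 3: memory parameters of the energy-expenditure adaptation
#'
#' Fits the adaptation gain and the two trailing-average windows
#' (`mem_gain`, `tau1`, `tau2`) on the weekly-varying hypocaloric group with
#' all other parameters fixed (steps 1-2). The windows are optimized on a
#' continuous scale through the reparameterization
#' `(log k, log tau1, log(tau2 - tau1))`, which enforces `tau1 < tau2`;
#' reported values are continuous days (round for tabulation).
#'
#' @param h1_records hypocaloric cohort records (shared schedule).
#' @param schedule the group's [feeding_schedule()] (with lead-in).
#' @param p parameter set carrying steps 1-2; its memory trio is the
#'   starting guess.
#' @param dt integrator step, minutes.
#' @param weights RSS component weights.
#' @param restarts,maxit,seed optimizer controls.
#' @param tau2_starts optional vector of long-window starting values (days):
#'   Nelder-Mead is seeded from each in turn and the best minimum is kept,
#'   guarding against secondary minima of the window search.
#' @return a `fit_result` with estimates `mem_gain`, `tau1`, `tau2`.
#' @export
fit_step3 <- function(h1_records, schedule, p, dt = 1,
                      weights = c(bw = 1, fat = 1, intake = 0),
                      restarts = 3, maxit = 300, seed = 1,
                      tau2_starts = NULL) {
  objective <- make_step3_objective(h1_records, schedule, p, dt, weights)
  obj_trans <- function(theta) {
    # theta = (k, tau1, dtau) after exponentiation by nm_restarts
    objective(theta[1], theta[2], theta[2] + theta[3])
  }
  if (is.null(tau2_starts)) tau2_starts <- p[["tau2"]]
  fit <- NULL
  for (t2s in tau2_starts) {
    tau1s <- min(p[["tau1"]], t2s / 2)
    start <- c(k = p[["mem_gain"]], tau1 = tau1s, dtau = t2s - tau1s)
    f <- nm_restarts(obj_trans, start, restarts = restarts, maxit = maxit,
                     seed = seed)
    if (is.null(fit) || f$value < fit$value) fit <- f
  }
  est <- c(mem_gain = unname(fit$par[["k"]]), tau1 = unname(fit$par[["tau1"]]),
           tau2 = unname(fit$par[["tau1"]] + fit$par[["dtau"]]))
  n_pts <- sum(vapply(h1_records, function(r) nrow(r$weekly_weights) + 1L,
                      integer(1)))
  fit_result("step3", est, fit$value, n_pts, 3L, fit$iterations,
             fit$converged)
}

#' Fit the constant-expenditure (no-memory) model variant
#'
#' One-dimensional fit of the constant rate of energy expenditure on a
#' hypocaloric group, with the memory switched off; the counterpart of
#' [fit_step3()] for AIC comparison.
#'
#' @param records cohort records (shared schedule).
#' @param schedule the group's [feeding_schedule()].
#' @param p parameter set (its `lambda0` is the starting guess).
#' @param dt integrator step, minutes.
#' @param weights RSS component weights.
#' @return a `fit_result` with a single `lambda0` estimate.
#' @export
fit_lambda_constant <- function(records, schedule, p, dt = 1,
                                weights = c(bw = 1, fat = 1, intake = 0)) {
  obj <- function(loglam) {
    pv <- as.numeric(p); names(pv) <- names(p)
    pv["lambda0"] <- exp(loglam)
    p2 <- do.call(model_parameters, as.list(pv))
    sim <- predict_cohort(records, schedule, p2, dt, memory_on = FALSE)
    rss_records(records, sim, weights)
  }
  opt <- stats::optimize(obj, log(p[["lambda0"]]) + c(-1, 1), tol = 1e-8)
  n_pts <- sum(vapply(records, function(r) nrow(r$weekly_weights) + 1L,
                      integer(1)))
  fit_result("constant-lambda", c(lambda0 = exp(opt$minimum)), opt$objective,
             n_pts, 1L, NA_integer_, TRUE)
}

#' AIC comparison of the memory and constant-expenditure variants
#'
#' Simulates both fitted variants on a group's observations and returns the
#' per-variant RSS and AIC. The memory variant carries 3 estimated
#' parameters (gain and two windows), the constant variant 1 (its refitted
#' rate).
#'
#' @param records the group's cohort records.
#' @param schedule the group's [feeding_schedule()].
#' @param p_memory parameter set with the fitted memory trio.
#' @param lambda_const the constant variant's fitted rate, min^-1.
#' @param dt integrator step, minutes.
#' @param weights RSS component weights.
#' @return data.frame with one row per variant: `model`, `rss`, `n_points`,
#'   `n_params`, `aic`.
#' @export
compare_aic <- function(records, schedule, p_memory, lambda_const, dt = 1,
                        weights = c(bw = 1, fat = 1, intake = 0)) {
  sim_mem <- predict_cohort(records, schedule, p_memory, dt)
  pv <- as.numeric(p_memory); names(pv) <- names(p_memory)
  pv["lambda0"] <- lambda_const
  p_const <- do.call(model_parameters, as.list(pv))
  sim_const <- predict_cohort(records, schedule, p_const, dt,
                              memory_on = FALSE)
  rss_mem <- rss_records(records, sim_mem, weights)
  rss_const <- rss_records(records, sim_const, weights)
  n_pts <- sum(vapply(records, function(r) nrow(r$weekly_weights) + 1L,
                      integer(1)))
  data.frame(model = c("memory", "no_memory"),
             rss = c(rss_mem, rss_const),
             n_points = n_pts, n_params = c(3L, 1L),
             aic = c(aic(rss_mem, n_pts, 3L), aic(rss_const, n_pts, 1L)))
}

#' Rejection-ABC posterior summary for the memory parameters
#'
#' Uniform sampling around the point estimates of `(mem_gain, tau1, tau2)`,
#' accepting draws whose RSS falls below `threshold_factor` times the
#' optimized minimum; reports the accepted draws and their mean and standard
#' deviation per parameter. Draws violating `tau1 < tau2` are rejected
#' outright.
#'
#' @param objective a function `(k, tau1, tau2) -> RSS`, e.g. from
#'   [make_step3_objective()].
#' @param point_estimate named numeric `mem_gain`, `tau1`, `tau2`.
#' @param prior_halfwidths half-widths of the uniform priors as fractions of
#'   the point estimates (default 0.5, i.e. +/-50%).
#' @param n_draws number of prior draws.
#' @param threshold_factor acceptance threshold as a multiple of the minimal
#'   RSS (default 1.3).
#' @param rss_min optional precomputed RSS at the point estimate.
#' @param seed integer seed.
#' @return an object of class `"abc_result"`: list with `draws` (data.frame
#'   of all draws with their RSS and acceptance flag), `threshold`,
#'   `summary` (mean and sd per parameter over accepted draws).
#' @export
abc_sample <- function(objective, point_estimate, prior_halfwidths = 0.5,
                       n_draws = 200, threshold_factor = 1.3, rss_min = NULL,
                       seed = 1) {
  stopifnot(threshold_factor >= 1, n_draws >= 1)
  pe <- point_estimate[c("mem_gain", "tau1", "tau2")]
  if (anyNA(pe)) stop("point_estimate must name mem_gain, tau1, tau2")
  hw <- rep_len(prior_halfwidths, 3)
  if (is.null(rss_min))
    rss_min <- objective(pe[["mem_gain"]], pe[["tau1"]], pe[["tau2"]])
  threshold <- threshold_factor * rss_min
  draws <- withr_seed(seed, {
    m <- matrix(runif(3 * n_draws, -1, 1), ncol = 3)
    sweep(1 + sweep(m, 2, hw, `*`), 2, as.numeric(pe), `*`)
  })
  colnames(draws) <- c("mem_gain", "tau1", "tau2")
  ok_order <- draws[, "tau1"] < draws[, "tau2"] & draws[, "mem_gain"] > 0 &
    draws[, "tau1"] > 0
  rss <- rep(NA_real_, n_draws)
  for (i in seq_len(n_draws))
    if (ok_order[i])
      rss[i] <- objective(draws[i, 1], draws[i, 2], draws[i, 3])
  accepted <- !is.na(rss) & rss < threshold
  if (!any(accepted))
    stop("no accepted draws; widen the prior or raise the threshold factor")
  acc <- draws[accepted, , drop = FALSE]
  structure(list(
    draws = data.frame(draws, rss = rss, accepted = accepted),
    threshold = threshold, rss_min = rss_min,
    summary = data.frame(parameter = colnames(draws),
                         mean = colMeans(acc),
                         sd = apply(acc, 2, sd),
                         row.names = NULL)),
    class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("Rejection ABC: %d/%d draws accepted (RSS < %.4g)\n",
              sum(x$draws$accepted), nrow(x$draws), x$threshold))
  print(x$summary)
  invisible(x)
}
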