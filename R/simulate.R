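# Simulation driver: integrates the full system over a feeding schedule and
# packages the result as a tidy trajectory.

#' Simulate the full model over a feeding schedule
#'
#' Fixed-step RK4 at `dt` minutes with one food-deposition event per day
#' (leftovers are removed at the next servicing) and a ring buffer of
#' per-step consumed energy feeding the two memory windows. Before the
#' simulation starts the buffer is pre-filled with a constant ad-libitum
#' level intake (the experiment's lead-in regime), unless an explicit
#' per-step history is carried over from a previous run.
#'
#' @param p a [model_parameters()] set.
#' @param s a [feeding_schedule()].
#' @param init a [model_state()], e.g. from [initial_state()].
#' @param dt step size, minutes; must divide 1440.
#' @param memory_on if `FALSE` the rate of energy expenditure stays frozen at
#'   its initial value (the constant-expenditure model variant).
#' @param stride record one state snapshot every `stride` steps (the snapshot
#'   grid always contains the day boundaries when `stride * dt` divides
#'   1440).
#' @param q_prehist constant pre-history intake flux, kJ/min, used to seed
#'   the memory buffer; defaults to the ad-libitum equilibrium intake stored
#'   by [initial_state()], falling back to the current intake implied by
#'   `init`.
#' @param prehist_buffer optional per-step consumed-energy history
#'   (chronological, `tau2 * 1440 / dt` entries) carried over from a previous
#'   trajectory; overrides `q_prehist`.
#' @return an object of class `"trajectory"`: a list with `states` (tidy
#'   data.frame: `time_min`, the eight state variables, `BW_g`, cumulative
#'   `consumed_kJ`), `daily`
#'   (data.frame: `day`, `delivered_kJ`, `consumed_kJ`, `removed_kJ`),
#'   `final_state`, `final_buffer`, `dt`, `schedule`, `params`.
#' @export
simulate <- function(p, s, init, dt = 1, memory_on = TRUE, stride = 60,
                     q_prehist = NULL, prehist_buffer = NULL) {
  validate_parameters(p)
  stopifnot(inherits(s, "feeding_schedule"))
  if (is.null(q_prehist)) {
    q_prehist <- attr(init, "q0")
    if (is.null(q_prehist))
      q_prehist <- food_intake_rate(init[["H"]], max(init[["Favail"]], init[["H"]]), p)
  }
  res <- .sim_full_cpp(as.numeric(init)[seq_along(STATE_NAMES)],
                       as.numeric(p[PARAM_NAMES]),
                       s$daily_grams * s$energy_density,
                       s$unlimited, dt, as.integer(stride), memory_on,
                       q_prehist, prehist_buffer)
  states <- as.data.frame(res$states)
  names(states) <- STATE_NAMES
  states <- cbind(time_min = res$time_min, states,
                  BW_g = states$F + states$FFM,
                  consumed_kJ = res$cum_consumed)
  daily <- data.frame(day = seq_along(res$daily_consumed),
                      delivered_kJ = res$daily_delivered,
                      consumed_kJ = res$daily_consumed,
                      removed_kJ = res$daily_removed)
  structure(list(states = states, daily = daily,
                 final_state = setNames(res$final_state, STATE_NAMES),
                 final_buffer = res$final_buffer,
                 dt = dt, stride = stride, schedule = s, params = p,
                 memory_on = memory_on),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d days at dt = %g min; final BW %.1f g\n",
              nrow(x$daily), x$dt,
              x$final_state[["F"]] + x$final_state[["FFM"]]))
  invisible(x)
}

#' Weekly body-weight observations
#'
#' Samples body weight once every 7 days, at the configured weigh-day
#' offset, counting weeks from the end of the schedule's lead-in.
#'
#' @param tr a [simulate()] trajectory.
#' @param weigh_day_offset day within the week at which the animal is
#'   weighed (default 7: end of each week).
#' @return data.frame with `week` and `BW_g`.
#' @export
observe_weekly_weights <- function(tr, weigh_day_offset = 7) {
  lead <- tr$schedule$lead_in_days
  n_days <- nrow(tr$daily) - lead
  if (n_days < 7) stop("trajectory must cover at least one post-lead-in week")
  weeks <- seq_len(n_days %/% 7)
  t_obs <- (lead + (weeks - 1) * 7 + weigh_day_offset) * MINUTES_PER_DAY
  idx <- match(t_obs, tr$states$time_min)
  if (anyNA(idx))
    stop("weigh times not on the recorded grid; use a stride dividing 1440/dt")
  data.frame(week = weeks, BW_g = tr$states$BW_g[idx])
}

#' Daily consumed-food observations
#'
#' Per-day consumed grams (consumed kJ divided by the diet energy density).
#' The cumulative series is non-decreasing and never exceeds the cumulative
#' delivered amount.
#'
#' @param tr a [simulate()] trajectory.
#' @return data.frame with `day`, `consumed_g`, `allocated_g`, `leftover_g`.
#' @export
observe_daily_intake <- function(tr) {
  ed <- tr$schedule$energy_density
  data.frame(day = tr$daily$day,
             consumed_g = tr$daily$consumed_kJ / ed,
             allocated_g = tr$schedule$daily_grams,
             leftover_g = pmax(0, tr$schedule$daily_grams -
                                 tr$daily$consumed_kJ / ed))
}

#' Continue a trajectory under further schedules
#'
#' Concatenates simulations, carrying over the final state and the intake
#' history buffer, so the memory windows see the true past across the seam.
#'
#' @param tr a [simulate()] trajectory.
#' @param ... further [feeding_schedule()]s (zero schedules return `tr`).
#' @return a [simulate()] trajectory covering the concatenated horizon.
#' @export
extend_scenario <- function(tr, ...) {
  more <- list(...)
  if (!length(more)) return(tr)
  out <- tr
  for (s2 in more) {
    stopifnot(inherits(s2, "feeding_schedule"))
    init2 <- do.call(model_state, as.list(out$final_state))
    seg <- simulate(out$params, s2, init2, dt = out$dt,
                    memory_on = out$memory_on, stride = out$stride,
                    prehist_buffer = out$final_buffer)
    offset_min <- max(out$states$time_min)
    seg$states$time_min <- seg$states$time_min + offset_min
    seg$states$consumed_kJ <- seg$states$consumed_kJ +
      max(out$states$consumed_kJ)
    seg$daily$day <- seg$daily$day + nrow(out$daily)
    out <- structure(list(
      states = rbind(out$states, seg$states[-1, ]),
      daily = rbind(out$daily, seg$daily),
      final_state = seg$final_state, final_buffer = seg$final_buffer,
      dt = out$dt, stride = out$stride,
      schedule = feeding_schedule(
        c(out$schedule$daily_grams, s2$daily_grams),
        unlimited = c(out$schedule$unlimited, s2$unlimited),
        energy_density = out$schedule$energy_density,
        lead_in_days = out$schedule$lead_in_days),
      params = out$params, memory_on = out$memory_on),
      class = "trajectory")
  }
  out
}

#' Export a trajectory as tidy CSV
#'
#' @param tr a [simulate()] trajectory.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  df <- tr$states
  names(df) <- c("time_min", "F_g", "FFM_g", "Favail_kJ", "H_kJ", "L_ng",
                 "G_g", "Ghr_pgml", "lambda_permin", "BW_g", "consumed_kJ")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
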