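# Synthetic rat cohorts with the study's measurement structure: weekly body
# weights, daily consumed food, terminal fat mass observed through a
# retroperitoneal-fat (rWAT) regression.

# Synthetic rWAT calibration: total body lipid (g) = RWAT_A + RWAT_B * rWAT.
# The coefficients are this package's synthetic stand-in for a gravimetric
# calibration; the transform is exactly invertible so the estimation pipeline
# is unaffected by the choice.
RWAT_A <- 6.0
RWAT_B <- 5.0

#' Total body fat from a retroperitoneal fat-pad weight (synthetic calibration)
#' @param rwat retroperitoneal fat-pad weight, g.
#' @return total body lipid, g.
#' @export
rwat_to_fat <- function(rwat) RWAT_A + RWAT_B * rwat

#' Retroperitoneal fat-pad weight from total body fat (synthetic calibration)
#' @param fat total body lipid, g.
#' @return retroperitoneal fat-pad weight, g.
#' @export
fat_to_rwat <- function(fat) (fat - RWAT_A) / RWAT_B

#' Cohort specification
#'
#' @param n_per_group rats per group (study design: 6).
#' @param cv inter-individual lognormal coefficient of variation applied to
#'   `lambda0` and the four hunger coefficients.
#' @param weight_noise_sd Gaussian sd added to weekly body weights, g.
#' @param intake_noise_sd Gaussian sd added to daily consumed food, g
#'   (truncated into [0, allocated]).
#' @param bw0_mean,bw0_sd initial body-weight distribution, g.
#' @param f0_mean,f0_sd initial fat-mass distribution, g.
#' @param seed integer seed.
#' @return a list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = 6, cv = 0, weight_noise_sd = 5,
                        intake_noise_sd = 0.5, bw0_mean = 400, bw0_sd = 15,
                        f0_mean = 70, f0_sd = 8, seed = 1) {
  stopifnot(n_per_group >= 1, cv >= 0, weight_noise_sd >= 0,
            intake_noise_sd >= 0, bw0_sd >= 0, f0_sd >= 0)
  structure(list(n_per_group = n_per_group, cv = cv,
                 weight_noise_sd = weight_noise_sd,
                 intake_noise_sd = intake_noise_sd,
                 bw0_mean = bw0_mean, bw0_sd = bw0_sd,
                 f0_mean = f0_mean, f0_sd = f0_sd, seed = seed),
            class = "cohort_spec")
}

#' Perturb a parameter set for one individual
#'
#' Lognormal multiplicative perturbation (coefficient of variation `cv`) of
#' the individual-level parameters `lambda0` and the four hunger
#' coefficients; `cv = 0` returns the base set unchanged. Deterministic per
#' seed.
#'
#' @param base a [model_parameters()] set.
#' @param cv coefficient of variation.
#' @param seed integer seed.
#' @return a [model_parameters()] set.
#' @export
sample_individual <- function(base, cv, seed) {
  if (cv == 0) return(base)
  varying <- c("lambda0", "hunger_ghrelin", "hunger_leptin",
               "hunger_glucose", "hunger_relax")
  sdlog <- sqrt(log(1 + cv^2))
  mult <- withr_seed(seed, exp(rnorm(length(varying), -sdlog^2 / 2, sdlog)))
  out <- as.numeric(base)
  names(out) <- names(base)
  out[varying] <- out[varying] * mult
  do.call(model_parameters, as.list(out))
}

#' Generate a synthetic cohort
#'
#' Simulates each rat with its sampled parameters and group schedule (the
#' schedules should carry the 5-day ad-libitum lead-in), then applies the
#' study's observation model: weekly body weights with Gaussian noise, daily
#' consumed food with Gaussian noise truncated into [0, allocated], and a
#' terminal fat mass reported through the rWAT regression and its inverse.
#'
#' @param spec a [cohort_spec()].
#' @param schedules named list of [feeding_schedule()]s, one per group
#'   (names become group labels, e.g. `list(AL = ..., H1 = ...)`).
#' @param base a [model_parameters()] set.
#' @param dt integrator step, minutes.
#' @return a list of class `"cohort"`: one record per rat with fields
#'   `rat_id`, `group`, `params`, `BW0`, `F0`, `weekly_weights` (data.frame
#'   week, BW_g), `daily_intake` (data.frame day, consumed_g, allocated_g),
#'   `terminal_fat`, `terminal_rwat`, and the noiseless `trajectory`.
#' @export
generate_cohort <- function(spec, schedules, base = model_parameters(),
                            dt = 1) {
  stopifnot(inherits(spec, "cohort_spec"), length(schedules) >= 1,
            !is.null(names(schedules)))
  rats <- list()
  rid <- 0L
  for (g in names(schedules)) {
    sch <- schedules[[g]]
    for (i in seq_len(spec$n_per_group)) {
      rid <- rid + 1L
      seed_i <- spec$seed * 10000L + rid
      draws <- withr_seed(seed_i, list(
        bw0 = rnorm(1, spec$bw0_mean, spec$bw0_sd),
        f0 = rnorm(1, spec$f0_mean, spec$f0_sd),
        wnoise = rnorm(64, 0, spec$weight_noise_sd),
        inoise = rnorm(length(sch$daily_grams), 0, spec$intake_noise_sd)
      ))
      BW0 <- max(draws$bw0, 2 * spec$f0_mean)
      F0 <- min(max(draws$f0, 10), 0.5 * BW0)
      p_i <- sample_individual(base, spec$cv, seed_i + 1L)
      init <- initial_state(BW0, F0, p_i)
      tr <- simulate(p_i, sch, init, dt = dt)

      ww <- observe_weekly_weights(tr)
      ww$BW_g <- ww$BW_g + draws$wnoise[seq_len(nrow(ww))]
      di <- observe_daily_intake(tr)
      di$consumed_g <- pmin(pmax(di$consumed_g + draws$inoise, 0),
                            ifelse(tr$schedule$unlimited, Inf, di$allocated_g))
      terminal_fat <- rwat_to_fat(fat_to_rwat(tr$final_state[["F"]]))

      rats[[rid]] <- list(rat_id = rid, group = g, params = p_i,
                          BW0 = BW0, F0 = F0,
                          weekly_weights = ww,
                          daily_intake = di[, c("day", "consumed_g",
                                                "allocated_g")],
                          terminal_fat = terminal_fat,
                          terminal_rwat = fat_to_rwat(terminal_fat),
                          trajectory = tr)
    }
  }
  structure(rats, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, "", "group")
  cat("Synthetic cohort:", length(x), "rats (",
      paste(sprintf("%s: %d", names(table(groups)), table(groups)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Subset a cohort by group label
#' @param cohort a [generate_cohort()] cohort.
#' @param group group label, e.g. `"AL"`.
#' @return a `cohort` containing only that group's rats.
#' @export
cohort_group <- function(cohort, group) {
  out <- Filter(function(r) r$group == group, cohort)
  if (!length(out)) stop("cohort has no group ", group)
  structure(out, class = "cohort")
}

#' Write a cohort to CSV (measurements + metadata)
#'
#' Two files: `<path>_measurements.csv` (rat_id, day, kind in {weight,
#' intake, terminal_fat}, value_g) and `<path>_meta.csv` (rat_id, group,
#' BW0, F0). Trajectories and per-rat parameters are not serialized.
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param path file stem.
#' @return the measurement-file path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  meas <- do.call(rbind, lapply(cohort, function(r) {
    rbind(
      data.frame(rat_id = r$rat_id, day = r$weekly_weights$week * 7,
                 kind = "weight", value_g = r$weekly_weights$BW_g),
      data.frame(rat_id = r$rat_id, day = r$daily_intake$day,
                 kind = "intake", value_g = r$daily_intake$consumed_g),
      if (!is.null(r$terminal_fat) && !is.na(r$terminal_fat))
        data.frame(rat_id = r$rat_id, day = max(r$daily_intake$day),
                   kind = "terminal_fat", value_g = r$terminal_fat)
    )
  }))
  meta <- do.call(rbind, lapply(cohort, function(r)
    data.frame(rat_id = r$rat_id, group = r$group, BW0 = r$BW0, F0 = r$F0)))
  write.csv(meas, paste0(path, "_measurements.csv"), row.names = FALSE)
  write.csv(meta, paste0(path, "_meta.csv"), row.names = FALSE)
  invisible(paste0(path, "_measurements.csv"))
}

#' Read a cohort written by [write_cohort()]
#'
#' Restores the observation tables (not trajectories or per-rat parameters).
#' A missing terminal fat mass is allowed (weekly-weights-only fitting).
#'
#' @param path file stem used in [write_cohort()].
#' @return a `cohort`.
#' @export
read_cohort <- function(path) {
  meas <- read.csv(paste0(path, "_measurements.csv"))
  meta <- read.csv(paste0(path, "_meta.csv"))
  if (any(meas$value_g < 0 & meas$kind == "weight"))
    stop("negative weight at measurement row ",
         which(meas$value_g < 0 & meas$kind == "weight")[1])
  rats <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$rat_id[i]
    m <- meas[meas$rat_id == id, ]
    w <- m[m$kind == "weight", ]
    it <- m[m$kind == "intake", ]
    tf <- m[m$kind == "terminal_fat", ]
    list(rat_id = id, group = meta$group[i], params = NULL,
         BW0 = meta$BW0[i], F0 = meta$F0[i],
         weekly_weights = data.frame(week = w$day / 7, BW_g = w$value_g),
         daily_intake = data.frame(day = it$day, consumed_g = it$value_g,
                                   allocated_g = NA_real_),
         terminal_fat = if (nrow(tf)) tf$value_g[1] else NA_real_,
         terminal_rwat = if (nrow(tf)) fat_to_rwat(tf$value_g[1]) else NA_real_,
         trajectory = NULL)
  })
  structure(rats, class = "cohort")
}
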