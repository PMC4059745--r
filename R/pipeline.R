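# High-level workflow entry points: each writes CSV outputs plus a run
# manifest (seed, parameter hash, settings) sufficient to re-run
# bit-identically. These functions are the package's command surface; call
# them from Rscript one-liners for shell use.

write_manifest <- function(out_dir, seed, p, extra = list()) {
  pf <- file.path(out_dir, "parameters.txt")
  write_parameters(p, pf)
  hash <- sum(as.numeric(p) * seq_along(p)) # cheap content fingerprint
  lines <- c(sprintf("package_version = %s",
                     as.character(utils::packageVersion("metmemo"))),
             sprintf("seed = %d", seed),
             sprintf("parameter_file = %s", basename(pf)),
             sprintf("parameter_checksum = %.10g", hash),
             vapply(names(extra), function(k)
               sprintf("%s = %s", k, format(extra[[k]])), ""))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Run a simulation and write trajectory + observation CSVs
#'
#' @param schedule a [feeding_schedule()] (with any lead-in already
#'   prepended).
#' @param out_dir output directory (created if needed).
#' @param p a [model_parameters()] set.
#' @param BW0,F0 initial biometrics, g.
#' @param dt integrator step, minutes.
#' @param memory_on memory flag; `FALSE` runs the constant-expenditure
#'   variant.
#' @param seed recorded in the manifest (the simulator itself is
#'   deterministic).
#' @param stride snapshot stride, steps.
#' @return the trajectory, invisibly; writes `trajectory.csv`,
#'   `weekly_weights.csv`, `daily_intake.csv`, `parameters.txt`,
#'   `manifest.txt`.
#' @export
run_simulation <- function(schedule, out_dir, p = model_parameters(),
                           BW0 = 400, F0 = 70, dt = 1, memory_on = TRUE,
                           seed = 1, stride = 60) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  init <- initial_state(BW0, F0, p)
  tr <- simulate(p, schedule, init, dt = dt, memory_on = memory_on,
                 stride = stride)
  write_trajectory(tr, file.path(out_dir, "trajectory.csv"))
  write.csv(observe_weekly_weights(tr),
            file.path(out_dir, "weekly_weights.csv"), row.names = FALSE)
  write.csv(observe_daily_intake(tr),
            file.path(out_dir, "daily_intake.csv"), row.names = FALSE)
  write_manifest(out_dir, seed, p,
                 list(dt = dt, memory_on = memory_on, BW0 = BW0, F0 = F0))
  invisible(tr)
}

#' Run the full three-step estimation pipeline on a cohort
#'
#' Steps 1-3 in order (ad-libitum group for steps 1-2, weekly-varying
#' hypocaloric group for step 3), followed by the AIC comparison of the
#' memory and constant-expenditure variants on every group present. Writes a
#' parameter table, an AIC table and a manifest.
#'
#' @param cohort a [generate_cohort()] cohort containing at least groups
#'   `"AL"` and `"H1"`.
#' @param schedules named list of the groups' schedules (as used for
#'   generation).
#' @param out_dir output directory.
#' @param p starting parameter set.
#' @param dt integrator step for full-model fits, minutes.
#' @param seed optimizer-jitter seed.
#' @param restarts Nelder-Mead restarts per step.
#' @return list with the three `fit_result`s, the fitted parameter set and
#'   the AIC table, invisibly.
#' @export
run_fit_pipeline <- function(cohort, schedules, out_dir,
                             p = model_parameters(), dt = 1, seed = 1,
                             restarts = 3) {
  if (!all(c("AL", "H1") %in% vapply(cohort, `[[`, "", "group")))
    stop("cohort must contain groups AL and H1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  al <- cohort_group(cohort, "AL")
  h1 <- cohort_group(cohort, "H1")

  s1 <- fit_step1(al, p, lead_in_days = schedules$AL$lead_in_days,
                  restarts = restarts, seed = seed)
  pv <- as.numeric(p); names(pv) <- names(p)
  pv[names(s1$estimates)] <- s1$estimates
  p1 <- do.call(model_parameters, as.list(pv))

  s2 <- fit_step2(al, p1, schedules$AL, restarts = restarts, seed = seed)
  pv[names(s2$estimates)] <- s2$estimates
  p2 <- do.call(model_parameters, as.list(pv))

  s3 <- fit_step3(h1, schedules$H1, p2, dt = dt, restarts = restarts,
                  seed = seed)
  pv[names(s3$estimates)] <- s3$estimates
  p3 <- do.call(model_parameters, as.list(pv))

  groups <- unique(vapply(cohort, `[[`, "", "group"))
  aic_rows <- lapply(setdiff(groups, "AL"), function(g) {
    recs <- cohort_group(cohort, g)
    lam_c <- fit_lambda_constant(recs, schedules[[g]], p3, dt = dt)
    cmp <- compare_aic(recs, schedules[[g]], p3,
                       lam_c$estimates[["lambda0"]], dt = dt)
    cbind(group = g, cmp)
  })
  aic_table <- do.call(rbind, aic_rows)

  est_table <- data.frame(
    parameter = c(names(s1$estimates), names(s2$estimates),
                  names(s3$estimates)),
    value = c(s1$estimates, s2$estimates, s3$estimates),
    step = rep(c("step1", "step2", "step3"), c(5, 4, 3)))
  write.csv(est_table, file.path(out_dir, "fitted_parameters.csv"),
            row.names = FALSE)
  write.csv(aic_table, file.path(out_dir, "aic_table.csv"),
            row.names = FALSE)
  write_manifest(out_dir, seed, p3, list(dt = dt, restarts = restarts))
  invisible(list(step1 = s1, step2 = s2, step3 = s3, params = p3,
                 aic_table = aic_table))
}

#' Run the 16-week scenario comparison
#'
#' Continues each 8-week pattern with either the constant hypocaloric
#' pattern or itself, for 16 weeks total, and reports the final body
#' weights: the constant continuations converge to a common weight
#' regardless of the first 8 weeks, while repeating a high-amplitude pattern
#' drives further gains.
#'
#' @param out_dir output directory.
#' @param p a [model_parameters()] set.
#' @param BW0,F0 initial biometrics, g.
#' @param dt integrator step, minutes.
#' @param seed seed for the weekly-randomised pattern and the manifest.
#' @return data.frame `scenario`, `final_BW_g`, invisibly; writes
#'   `scenarios.csv` and a manifest.
#' @export
run_scenarios <- function(out_dir, p = model_parameters(), BW0 = 400,
                          F0 = 70, dt = 1, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  first <- list(H0 = build_H0(56), H1 = build_H1(56, seed = seed),
                H4 = build_H4(56))
  combos <- list(
    c("H0", "H0"), c("H1", "H0"), c("H4", "H0"),
    c("H1", "H1"), c("H4", "H4"))
  init <- initial_state(BW0, F0, p)
  rows <- lapply(combos, function(cmb) {
    tr <- simulate(p, with_lead_in(first[[cmb[1]]], 5), init, dt = dt)
    tr <- extend_scenario(tr, first[[cmb[2]]])
    data.frame(scenario = paste(cmb, collapse = "->"),
               final_BW_g = unname(tr$final_state[["F"]] +
                                     tr$final_state[["FFM"]]))
  })
  out <- do.call(rbind, rows)
  write.csv(out, file.path(out_dir, "scenarios.csv"), row.names = FALSE)
  write_manifest(out_dir, seed, p, list(dt = dt, BW0 = BW0, F0 = F0))
  invisible(out)
}
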