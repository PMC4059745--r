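# Estimation machinery: RSS bookkeeping, AIC, optimizer plumbing, ABC.
# The expensive end-to-end recovery runs live in test-acceptance.R.

p <- default_params

fake_record <- function(bw, fat = 50, intake = NULL) {
  list(weekly_weights = data.frame(week = seq_along(bw), BW_g = bw),
       terminal_fat = fat,
       daily_intake = if (is.null(intake)) data.frame(day = integer(),
                                                      consumed_g = numeric())
       else data.frame(day = seq_along(intake), consumed_g = intake))
}

test_that("residual sum of squares counts matched points only once", {
  o <- list(fake_record(c(400, 410, 420)))
  s <- list(fake_record(c(400, 410, 420)))
  expect_equal(rss_records(o, s), 0)
  s2 <- list(fake_record(c(400, 412, 420)))
  expect_equal(rss_records(o, s2), 4)
  # permutation invariance over rats
  o2 <- list(fake_record(c(400, 410)), fake_record(c(380, 385)))
  s3 <- list(fake_record(c(401, 410)), fake_record(c(380, 388)))
  expect_equal(rss_records(o2, s3), rss_records(rev(o2), rev(s3)))
  # component weights
  expect_equal(rss_records(o, list(fake_record(c(400, 410, 420), fat = 52))),
               4)
  expect_equal(rss_records(o, list(fake_record(c(400, 410, 420), fat = 52)),
                           weights = c(bw = 1, fat = 3, intake = 0)), 12)
  # mismatched observation grids are an error
  s4 <- list(fake_record(c(400, 410)))
  s4[[1]]$weekly_weights$week <- c(2, 3)
  o4 <- list(fake_record(c(400, 410)))
  expect_error(rss_records(o4, s4), "do not match")
})

test_that("AIC is the least-squares form with the parameter penalty", {
  expect_equal(aic(100, 50, 3), 50 * log(2) + 6)
  expect_lt(aic(50, 50, 3), aic(100, 50, 3))      # better fit, lower AIC
  expect_equal(aic(100, 50, 4) - aic(100, 50, 3), 2) # +2 per extra parameter
  expect_identical(aic(0, 50, 3), -Inf)            # perfect-fit sentinel
  expect_error(aic(10, 3, 5))
})

test_that("log-scale Nelder-Mead restarts find a quadratic optimum", {
  target <- c(a = 2, b = 0.5)
  obj <- function(theta) sum((log(theta) - log(target))^2)
  fit <- metmemo:::nm_restarts(obj, c(a = 1, b = 1), restarts = 3,
                               maxit = 500, seed = 2)
  expect_equal(unname(fit$par), unname(target), tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("duplicated rats give identical per-rat step-1 estimates", {
  al <- noiseless_al()
  rec <- al$cohort[[1]]
  twin <- structure(list(rec, rec), class = "cohort")
  f <- fit_step1(twin, p, restarts = 1, maxit = 60, seed = 3)
  expect_equal(f$per_rat[[1]]$par, f$per_rat[[2]]$par)
  expect_gte(f$rss, 0)
  expect_equal(f$n_params, 5)
})

test_that("step-3 objective has its minimum at the generating parameters", {
  sch <- with_lead_in(build_H1(28, seed = 6), 2)
  spec <- cohort_spec(n_per_group = 2, cv = 0, weight_noise_sd = 0,
                      intake_noise_sd = 0, seed = 6)
  coh <- generate_cohort(spec, list(H1 = sch), p, dt = 4)
  obj <- metmemo:::make_step3_objective(coh, sch, p, dt = 4)
  at_truth <- obj(p[["mem_gain"]], p[["tau1"]], p[["tau2"]])
  expect_lt(at_truth, 1e-6)
  for (f in c(0.9, 1.1)) {
    expect_gt(obj(p[["mem_gain"]] * f, p[["tau1"]], p[["tau2"]]), at_truth)
    expect_gt(obj(p[["mem_gain"]], p[["tau1"]], p[["tau2"]] * f), at_truth)
  }
})

test_that("swapped window starting guesses still satisfy tau1 < tau2", {
  sch <- with_lead_in(build_H1(28, seed = 8), 2)
  spec <- cohort_spec(n_per_group = 1, cv = 0, weight_noise_sd = 0,
                      intake_noise_sd = 0, seed = 8)
  coh <- generate_cohort(spec, list(H1 = sch), p, dt = 4)
  # start with the windows inverted: tau1 guess 8, tau2 guess 1.5
  pstart <- params_with(c(tau1 = 8, tau2 = 8.5))
  f <- fit_step3(coh, sch, pstart, dt = 4, restarts = 1, maxit = 50,
                 tau2_starts = 1.5)
  expect_lt(f$estimates[["tau1"]], f$estimates[["tau2"]])
})

test_that("rejection ABC keeps draws under threshold and concentrates as it tightens", {
  # cheap analytic stand-in objective centred on the reference trio
  centre <- c(mem_gain = 9.05e-4, tau1 = 1, tau2 = 8)
  obj <- function(k, t1, t2)
    1 + ((k / centre[1] - 1)^2 + (t1 - 1)^2 + ((t2 - 8) / 4)^2)
  res <- abc_sample(obj, centre, prior_halfwidths = 0.5, n_draws = 400,
                    threshold_factor = 1.3, rss_min = 1, seed = 4)
  acc <- res$draws[res$draws$accepted, ]
  expect_true(all(acc$rss < res$threshold))
  expect_true(all(acc$tau1 < acc$tau2))
  expect_equal(res$summary$parameter, c("mem_gain", "tau1", "tau2"))
  # mean of the accepted cloud sits near the point estimate
  expect_lt(abs(res$summary$mean[3] - 8), res$summary$sd[3] + 0.5)
  # tighter threshold concentrates the cloud
  res_tight <- abc_sample(obj, centre, prior_halfwidths = 0.5, n_draws = 400,
                          threshold_factor = 1.02, rss_min = 1, seed = 4)
  expect_lt(sum(res_tight$draws$accepted), sum(res$draws$accepted))
  expect_lt(res_tight$summary$sd[3], res$summary$sd[3])
  # same seed reproduces the draws exactly
  res2 <- abc_sample(obj, centre, prior_halfwidths = 0.5, n_draws = 400,
                     threshold_factor = 1.3, rss_min = 1, seed = 4)
  expect_identical(res$draws, res2$draws)
  expect_error(abc_sample(function(...) 10, centre, n_draws = 10,
                          threshold_factor = 1.0001, rss_min = 1e-9),
               "no accepted draws")
})

test_that("ABC around the generating memory trio covers it within one sd", {
  sch <- with_lead_in(build_H1(28, seed = 12), 2)
  spec <- cohort_spec(n_per_group = 2, cv = 0, weight_noise_sd = 5,
                      intake_noise_sd = 0, seed = 12)
  coh <- generate_cohort(spec, list(H1 = sch), default_params, dt = 4)
  obj <- metmemo:::make_step3_objective(coh, sch, default_params, dt = 4)
  centre <- c(mem_gain = default_params[["mem_gain"]],
              tau1 = default_params[["tau1"]],
              tau2 = default_params[["tau2"]])
  res <- abc_sample(obj, centre, prior_halfwidths = 0.5, n_draws = 60,
                    threshold_factor = 1.3, seed = 12)
  expect_gt(sum(res$draws$accepted), 0)
  t2row <- res$summary[res$summary$parameter == "tau2", ]
  expect_lt(abs(t2row$mean - 8), t2row$sd + 1)
})
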