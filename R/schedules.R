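# Feeding schedules: daily food allocations per rat. Hypocaloric builders
# conserve the 56-day group total (1120 g) exactly, using integer-milligram
# arithmetic. Chow energy density defaults to 12.6 kJ/g.

#' Construct a feeding schedule
#'
#' @param daily_grams per-day allocations, g.
#' @param unlimited logical per day; unlimited days never exhaust
#'   availability (the gram figure is nominal).
#' @param energy_density diet energy density, kJ/g.
#' @param lead_in_days number of ad-libitum lead-in days prepended (metadata;
#'   the first `lead_in_days` entries are the lead-in).
#' @return an object of class `"feeding_schedule"`.
#' @export
feeding_schedule <- function(daily_grams, unlimited = rep(FALSE, length(daily_grams)),
                             energy_density = 12.6, lead_in_days = 0L) {
  daily_grams <- as.numeric(daily_grams)
  if (length(daily_grams) < 1) stop("schedule needs at least one day")
  if (any(!is.finite(daily_grams)) || any(daily_grams < 0))
    stop("daily allocations must be finite and non-negative")
  if (length(unlimited) != length(daily_grams))
    stop("unlimited flag must have one entry per day")
  if (energy_density <= 0) stop("energy density must be positive")
  structure(list(daily_grams = daily_grams, unlimited = as.logical(unlimited),
                 energy_density = energy_density,
                 lead_in_days = as.integer(lead_in_days)),
            class = "feeding_schedule")
}

#' @export
print.feeding_schedule <- function(x, ...) {
  n <- length(x$daily_grams)
  cat(sprintf(
    "Feeding schedule: %d days (%d lead-in), %.1f kJ/g, total %.3f g%s\n",
    n, x$lead_in_days, x$energy_density, sum(x$daily_grams),
    if (any(x$unlimited)) sprintf(" (%d unlimited days)", sum(x$unlimited)) else ""))
  invisible(x)
}

#' @export
length.feeding_schedule <- function(x) length(x$daily_grams)

#' Total allocated food over the restricted span
#'
#' Sum of daily allocations, excluding the lead-in days.
#' @param s a [feeding_schedule()].
#' @return grams.
#' @export
schedule_total <- function(s) {
  idx <- seq_along(s$daily_grams) > s$lead_in_days
  sum(s$daily_grams[idx])
}

#' Ad-libitum schedule
#'
#' Constant nominal allocation (default 25 g/day), flagged unlimited so the
#' simulator never exhausts availability.
#'
#' @param duration days.
#' @param grams_per_day nominal daily allocation, g.
#' @param energy_density diet energy density, kJ/g.
#' @return a [feeding_schedule()].
#' @export
build_AL <- function(duration, grams_per_day = 25, energy_density = 12.6) {
  if (duration < 1) stop("duration must be at least one day")
  feeding_schedule(rep(grams_per_day, duration),
                   unlimited = rep(TRUE, duration),
                   energy_density = energy_density)
}

#' Constant hypocaloric schedule (H0 pattern)
#'
#' The same amount every day at 80% of the ad-libitum allocation:
#' 20 g/day, totalling 1120 g over 56 days.
#'
#' @param duration days, multiple of 7.
#' @param grams_per_day daily allocation, g.
#' @param energy_density diet energy density, kJ/g.
#' @return a [feeding_schedule()].
#' @export
build_H0 <- function(duration = 56, grams_per_day = 20, energy_density = 12.6) {
  if (duration %% 7 != 0) stop("duration must be a multiple of 7 days")
  feeding_schedule(rep(grams_per_day, duration),
                   energy_density = energy_density)
}

# allocate `total_mg` over `nweeks` weekly blocks proportional to `w`,
# each block constant across its 7 days, exact to the milligram
# (largest-remainder rounding of the per-day milligram figures).
weekly_blocks_mg <- function(w, total_mg, nweeks) {
  daily_target_mg <- total_mg / 7               # sum of per-day mg over weeks
  ideal <- w / sum(w) * daily_target_mg         # per-week daily mg, fractional
  d <- floor(ideal)
  rem <- round(daily_target_mg - sum(d))
  if (rem > 0) {
    take <- order(ideal - d, decreasing = TRUE)[seq_len(rem)]
    d[take] <- d[take] + 1
  }
  rep(d, each = 7)                               # mg/day, constant within week
}

#' Weekly-randomised hypocaloric schedule (H1 pattern)
#'
#' Weekly amounts drawn around the 20 g/day mean (uniform multipliers in
#' `range`), constant within each week, and rescaled in integer-milligram
#' arithmetic so the grand total equals the constant schedule's total
#' exactly. Reproducible per seed.
#'
#' @param duration days, multiple of 7.
#' @param seed integer seed for the weekly draw.
#' @param mean_grams mean daily allocation, g.
#' @param range multiplier range for the weekly draw.
#' @param energy_density diet energy density, kJ/g.
#' @return a [feeding_schedule()].
#' @export
build_H1 <- function(duration = 56, seed = 1, mean_grams = 20,
                     range = c(0.5, 1.5), energy_density = 12.6) {
  if (duration %% 7 != 0) stop("duration must be a multiple of 7 days")
  nweeks <- duration %/% 7
  w <- withr_seed(seed, runif(nweeks, range[1], range[2]))
  total_mg <- round(mean_grams * 1000) * duration
  mg <- weekly_blocks_mg(w, total_mg, nweeks)
  feeding_schedule(mg / 1000, energy_density = energy_density)
}

#' Restriction-then-refeed hypocaloric schedule (H4 pattern)
#'
#' An important restriction for the first half (below 60% of the ad-libitum
#' average) followed by an excess of food for the second half, with the
#' grand total equal to the constant schedule's total exactly.
#'
#' @param duration days, multiple of 14 (default 56: 4 weeks + 4 weeks).
#' @param restriction_fraction fraction of the 25 g/day ad-libitum average
#'   delivered during the restriction phase; values at or above 0.6 trigger
#'   a warning (the restriction is meant to be severe).
#' @param al_grams ad-libitum average, g/day.
#' @param total_grams grand total to conserve, g (default matches
#'   `build_H0(duration)`).
#' @param energy_density diet energy density, kJ/g.
#' @return a [feeding_schedule()].
#' @export
build_H4 <- function(duration = 56, restriction_fraction = 0.48,
                     al_grams = 25, total_grams = 20 * duration,
                     energy_density = 12.6) {
  if (duration %% 14 != 0) stop("duration must split into two equal week blocks")
  if (restriction_fraction >= 0.6)
    warning("restriction_fraction >= 0.6: restriction phase is not severe")
  half <- duration %/% 2
  restr_mg <- round(restriction_fraction * al_grams * 1000)
  total_mg <- round(total_grams * 1000)
  refeed_mg_total <- total_mg - half * restr_mg
  if (refeed_mg_total < 0) stop("restriction phase exceeds the total budget")
  refeed_mg <- refeed_mg_total %/% half
  extra <- refeed_mg_total - refeed_mg * half    # spread remainder mg, one per day
  mg <- c(rep(restr_mg, half), rep(refeed_mg, half) + c(rep(1, extra), rep(0, half - extra)))
  feeding_schedule(mg / 1000, energy_density = energy_density)
}

#' Prepend ad-libitum lead-in days
#'
#' @param s a [feeding_schedule()].
#' @param days number of lead-in days (default 5, matching the study design).
#' @param grams_per_day nominal lead-in allocation, g.
#' @return a [feeding_schedule()] with `days` unlimited days prepended;
#'   the lead-in is excluded from [schedule_total()].
#' @export
with_lead_in <- function(s, days = 5, grams_per_day = 25) {
  if (days < 0) stop("days must be non-negative")
  if (days == 0) return(s)
  feeding_schedule(c(rep(grams_per_day, days), s$daily_grams),
                   unlimited = c(rep(TRUE, days), s$unlimited),
                   energy_density = s$energy_density,
                   lead_in_days = s$lead_in_days + days)
}

#' Write a feeding schedule to CSV
#'
#' Columns: `day` (1-based), `grams`, `unlimited` (0/1). The energy density
#' and lead-in length travel as comment header lines.
#'
#' @param s a [feeding_schedule()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# energy_density = %.10g", s$energy_density),
               sprintf("# lead_in_days = %d", s$lead_in_days),
               "day,grams,unlimited"), con)
  writeLines(sprintf("%d,%.10g,%d", seq_along(s$daily_grams), s$daily_grams,
                     as.integer(s$unlimited)), con)
  invisible(path)
}

#' Read a feeding schedule from CSV
#'
#' @param path file written by [write_schedule()]. A missing energy-density
#'   header falls back to 12.6 kJ/g with a warning.
#' @return a [feeding_schedule()].
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  get_hdr <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (!length(m)) return(NA_real_)
    as.numeric(sub(".*=\\s*", "", m[1]))
  }
  ed <- get_hdr("energy_density")
  if (is.na(ed)) {
    warning("missing energy_density header; defaulting to 12.6 kJ/g")
    ed <- 12.6
  }
  lead <- get_hdr("lead_in_days")
  if (is.na(lead)) lead <- 0
  df <- read.csv(text = paste(body, collapse = "\n"))
  need <- c("day", "grams", "unlimited")
  if (!all(need %in% names(df))) stop("schedule CSV must have columns day, grams, unlimited")
  if (any(!is.finite(df$grams)) || any(df$grams < 0)) {
    bad <- which(!is.finite(df$grams) | df$grams < 0)[1]
    stop("invalid grams value at data row ", bad)
  }
  df <- df[order(df$day), ]
  feeding_schedule(df$grams, unlimited = df$unlimited != 0,
                   energy_density = ed, lead_in_days = as.integer(lead))
}

# evaluate `expr` under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
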