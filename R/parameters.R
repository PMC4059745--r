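# Model parameters: 21 constants. Internal time unit is the minute; the two
# memory windows tau1/tau2 are expressed in days and converted at 1440 min/day.

#' Names of the 21 model parameters, in canonical order
#'
#' The order is the one used by the compiled integrator; keep in sync with
#' src/sim.cpp.
#' @keywords internal
PARAM_NAMES <- c(
  "theta_intake",    # min.kJ^-1, minutes needed to clear one kJ of intake backlog
  "rho_F",           # kJ.g^-1, energy density of fat mass
  "rho_FFM",         # kJ.g^-1, energy density of fat-free mass
  "part_K",          # kJ, partition constant (Forbes-type, energy scale)
  "part_A",          # -, partition constant
  "part_B",          # -, partition constant
  "part_c",          # g^-1, partition constant
  "lambda0",         # min^-1, baseline rate of energy expenditure
  "ghrelin_prod",    # pg.mL^-1.min^-1, maximal ghrelin production
  "ghrelin_clear",   # min^-1, ghrelin clearance
  "glucose_yield",   # g.kJ^-1, glucose produced per kJ consumed
  "glucose_clear",   # min^-1, glucose clearance
  "leptin_prod",     # ng.g^-1.min^-1, leptin production per g fat
  "leptin_clear",    # min^-1, leptin clearance
  "hunger_ghrelin",  # mL.kJ.min^-1.pg^-1, hunger production per unit ghrelin
  "hunger_leptin",   # ng^-1, leptin inhibition of hunger production
  "hunger_glucose",  # g, glucose half-saturation of hunger production
  "hunger_relax",    # min^-1.g^-1, glucose-driven hunger relaxation
  "mem_gain",        # kJ^-1, rate of adaptation of energy expenditure
  "tau1",            # day, short memory window
  "tau2"             # day, long memory window
)

#' Construct a validated parameter set
#'
#' Returns the default parameter set (the reference values of the calibrated
#' model), optionally overriding individual entries. All parameters must be
#' strictly positive, `tau1 < tau2` and `rho_F > rho_FFM`.
#'
#' @param ... named overrides, e.g. `model_parameters(tau2 = 10)`.
#' @return a named numeric vector of class `"model_parameters"`.
#' @examples
#' p <- model_parameters()
#' p[["tau2"]]
#' @export
model_parameters <- function(...) {
  p <- c(
    theta_intake   = 1.52,
    rho_F          = 39.3,
    rho_FFM        = 7.5,
    part_K         = 1964.4,
    part_A         = 2.2,
    part_B         = 1.6,
    part_c         = 0.269,
    lambda0        = 2.525e-5,
    ghrelin_prod   = 0.4025,
    ghrelin_clear  = 0.007,
    glucose_yield  = 0.039,
    glucose_clear  = 0.007,
    leptin_prod    = 0.126,
    leptin_clear   = 0.074,
    hunger_ghrelin = 4.02e-4,
    hunger_leptin  = 1.66e-4,
    hunger_glucose = 5.03e-1,
    hunger_relax   = 5.99e-3,
    mem_gain       = 9.05e-4,
    tau1           = 1,
    tau2           = 8
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(overrides), PARAM_NAMES)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- vapply(overrides, as.numeric, numeric(1))
  }
  validate_parameters(p)
  structure(p, class = "model_parameters")
}

#' @keywords internal
validate_parameters <- function(p) {
  stopifnot(all(PARAM_NAMES %in% names(p)))
  if (any(!is.finite(p)) || any(p < 0) ||
      any(p[setdiff(PARAM_NAMES, "mem_gain")] == 0))
    stop("all model parameters must be finite and strictly positive",
         " (mem_gain may be 0: the no-memory nested variant)")
  if (p[["tau1"]] >= p[["tau2"]])
    stop("tau1 must be smaller than tau2")
  if (p[["rho_F"]] <= p[["rho_FFM"]])
    stop("rho_F must exceed rho_FFM")
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters (21):\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

# units shown as comments in the serialized config
PARAM_UNITS <- c(
  theta_intake = "min.kJ^-1", rho_F = "kJ.g^-1", rho_FFM = "kJ.g^-1",
  part_K = "kJ", part_A = "-", part_B = "-", part_c = "g^-1",
  lambda0 = "min^-1", ghrelin_prod = "pg.mL^-1.min^-1",
  ghrelin_clear = "min^-1", glucose_yield = "g.kJ^-1",
  glucose_clear = "min^-1", leptin_prod = "ng.g^-1.min^-1",
  leptin_clear = "min^-1", hunger_ghrelin = "mL.kJ.min^-1.pg^-1",
  hunger_leptin = "ng^-1", hunger_glucose = "g", hunger_relax = "min^-1.g^-1",
  mem_gain = "kJ^-1", tau1 = "day", tau2 = "day"
)

#' Write a parameter set to a plain-text key-value file
#'
#' One `name = value` per line, with the unit as a trailing comment.
#'
#' @param p a `model_parameters` object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  validate_parameters(p)
  lines <- sprintf("%s = %.17g  # %s", names(p), as.numeric(p),
                   PARAM_UNITS[names(p)])
  writeLines(c("# metmemo model parameters", lines), path)
  invisible(path)
}

#' Read a parameter set from a plain-text key-value file
#'
#' @param path file written by [write_parameters()] (or edited by hand).
#' @return a `model_parameters` object.
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("malformed parameter line: ", lines[which(lengths(kv) != 2)[1]])
  nm <- trimws(vapply(kv, `[`, "", 1))
  val <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  if (anyNA(val)) stop("non-numeric parameter value for: ",
                       paste(nm[is.na(val)], collapse = ", "))
  do.call(model_parameters, as.list(setNames(val, nm)))
}
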