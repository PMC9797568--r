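#' Molar masses of the compounds tracked in the chemostat mass balance
#'
#' Glucose, ethanol, glycerol, CO2, lactate, pyruvate and acetate in g/mol.
#' Used to convert mass-based concentration differences (g/L) into the
#' molar specific rates (mmol g^-1 h^-1) conventional for chemostat
#' physiology. Override any entry via the `molar_mass` argument of
#' [specific_rate()].
#'
#' @format Named numeric vector, g/mol.
#' @export
molar_masses <- c(
  glucose  = 180.16,
  ethanol  = 46.07,
  glycerol = 92.09,
  co2      = 44.01,
  lactate  = 90.08,
  pyruvate = 88.06,
  acetate  = 60.05
)

#' Steady-state specific conversion rate in a chemostat
#'
#' At steady state the specific consumption or production rate of a compound
#' follows from the dilution rate and the feed/residual concentration gap:
#' q = 1000 * D * (feed - residual) / (MW * X), in mmol per gram dry weight
#' per hour. Consumption is reported negative by convention.
#'
#' @param D Dilution rate (h^-1), must be positive.
#' @param feed_conc Feed (reservoir) concentration, g/L.
#' @param residual_conc Residual (culture) concentration, g/L.
#' @param X Biomass concentration, g dry weight / L; must be positive.
#' @param molar_mass Molar mass of the compound, g/mol. Either a number or
#'   a name looked up in [molar_masses].
#' @param sign `"consumption"` (q returned negative) or `"production"`.
#' @return Specific rate q in mmol g^-1 h^-1.
#' @examples
#' specific_rate(0.1, 25, 0.69, 2.64, "glucose", "consumption")
#' @export
specific_rate <- function(D, feed_conc, residual_conc, X, molar_mass,
                          sign = c("consumption", "production")) {
  sign <- match.arg(sign)
  if (is.character(molar_mass)) {
    if (!molar_mass %in% names(molar_masses)) {
      stop("unknown compound '", molar_mass, "'; supply a numeric molar mass")
    }
    molar_mass <- molar_masses[[molar_mass]]
  }
  if (!is.finite(X) || X <= 0) stop("biomass X must be positive")
  if (!is.finite(molar_mass) || molar_mass <= 0) {
    stop("molar_mass must be positive")
  }
  if (feed_conc < 0 || residual_conc < 0) {
    stop("concentrations must be non-negative")
  }
  if (sign == "consumption" && feed_conc < residual_conc) {
    stop("feed concentration below residual for a consumed compound")
  }
  q <- 1000 * D * (feed_conc - residual_conc) / (molar_mass * X)
  if (sign == "consumption") -q else q
}

#' Biomass and ethanol yields on glucose
#'
#' Y_X/S = X / (feed - residual) in g DW per g glucose consumed;
#' Y_Eth/S = ethanol / (feed - residual) in g per g.
#'
#' @param D Dilution rate (h^-1); part of the steady-state record, checked
#'   positive but not otherwise used (yields are concentration ratios).
#' @param X Biomass, g DW/L.
#' @param feed_glucose,residual_glucose Glucose in feed and culture, g/L.
#' @param ethanol_conc Ethanol concentration, g/L.
#' @return Named list with `Y_XS` and `Y_EthS`.
#' @export
yields <- function(D, X, feed_glucose, residual_glucose, ethanol_conc) {
  if (D <= 0) stop("dilution rate D must be positive")
  consumed <- feed_glucose - residual_glucose
  if (consumed <= 0) stop("zero or negative glucose consumption")
  list(Y_XS = X / consumed, Y_EthS = ethanol_conc / consumed)
}

#' Percent change of a treated value relative to control
#'
#' 100 * (treated - control) / control. The published comparisons report
#' these rounded to the nearest integer; use `digits = 0` (the default in
#' [compare_conditions()]) to reproduce them.
#'
#' @param control,treated Values under the two conditions; control nonzero.
#' @return Percent change (unrounded).
#' @export
percent_change <- function(control, treated) {
  if (any(control == 0)) stop("control value is zero; percent change undefined")
  100 * (treated - control) / control
}

#' Log2 fold change between two positive values
#'
#' @param control,treated Positive values.
#' @return log2(treated / control).
#' @export
log2_fold_change <- function(control, treated) {
  if (any(control <= 0) || any(treated <= 0)) {
    stop("log2 fold change requires positive values")
  }
  log2(treated / control)
}

#' Compare physiology parameters between two chemostat conditions
#'
#' For each parameter present in both conditions, computes the percent
#' change relative to control (rounded for reporting) and, where both
#' values are positive, the log2 fold change. Percent changes of negative
#' rates (consumption convention) are computed on magnitudes so that a
#' faster consumption reports as an increase.
#'
#' @param physiology Data frame with columns `parameter`, `control`,
#'   `treated` (one row per parameter), e.g. as read from
#'   `system.file("extdata", "chemostat_physiology.csv", package = "coumnet")`.
#' @param digits Rounding for the reported percent change (default 0,
#'   matching the published integer percentages).
#' @return Data frame with columns `parameter`, `control`, `treated`,
#'   `percent_change`, `log2_fold_change`.
#' @export
compare_conditions <- function(physiology, digits = 0) {
  req <- c("parameter", "control", "treated")
  if (!all(req %in% names(physiology))) {
    stop("physiology table needs columns: ", paste(req, collapse = ", "))
  }
  out <- physiology[, req]
  ctrl <- abs(out$control)
  trt <- abs(out$treated)
  out$percent_change <- ifelse(
    ctrl == 0, NA_real_,
    round(100 * (trt - ctrl) / ctrl, digits)
  )
  out$log2_fold_change <- ifelse(
    ctrl > 0 & trt > 0, log2(trt / ctrl), NA_real_
  )
  out
}

#' Read a chemostat physiology table
#'
#' @param path CSV with columns `parameter`, `control`, `treated` (extra
#'   columns such as reported deviations are kept).
#' @return Data frame.
#' @export
read_physiology <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("parameter", "control", "treated")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("physiology file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}
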