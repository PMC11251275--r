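#' Assay constants for the NADH-coupled carboxylation assay
#'
#' Bundles the physical and experimental constants of the coupled
#' spectrophotometric assay in which rubisco carboxylation is read out as
#' NADH oxidation at 340 nm. Defaults are the published assay conditions:
#' NADH extinction coefficient 6220 M^-1 cm^-1, optical path 0.26 cm in the
#' microplate, two NADH oxidized per carboxylation, a CABP ladder of
#' 0, 0, 10, 20, 30, 90 nM, and a 15-min read at 2-s intervals at 30 degC
#' under 4% CO2 / 0.4% O2.
#'
#' @param epsilon340 Molar extinction coefficient of NADH at 340 nm
#'   (M^-1 cm^-1).
#' @param path_length Optical path length of the assay well (cm).
#' @param nadh_per_carboxylation NADH molecules oxidized per carboxylation
#'   event (dimensionless; 2 for the PGK/GAPDH couple).
#' @param rubp_conc RuBP concentration in the assay (mM).
#' @param nadh0 Initial NADH concentration (uM). Not stated in the source
#'   protocol; the default 200 uM keeps A340 ~ 0.32 and >= 10 min of
#'   linearity at typical rates.
#' @param temperature Assay temperature (degC).
#' @param co2_percent,o2_percent Gas phase composition (%).
#' @param cabp_ladder Ordered CABP concentrations (nM), one assay well each.
#'   Two zero-CABP replicates by default.
#' @param read_interval Read interval (s).
#' @param duration Total read duration (s).
#'
#' @return An object of class `assay_constants` (a validated list).
#' @examples
#' ac <- assay_constants()
#' ac$epsilon340 * ac$path_length # A340 per molar NADH
#' @export
assay_constants <- function(epsilon340 = 6220,
                            path_length = 0.26,
                            nadh_per_carboxylation = 2,
                            rubp_conc = 1,
                            nadh0 = 200,
                            temperature = 30,
                            co2_percent = 4,
                            o2_percent = 0.4,
                            cabp_ladder = c(0, 0, 10, 20, 30, 90),
                            read_interval = 2,
                            duration = 900) {
  x <- list(
    epsilon340 = epsilon340, path_length = path_length,
    nadh_per_carboxylation = nadh_per_carboxylation,
    rubp_conc = rubp_conc, nadh0 = nadh0, temperature = temperature,
    co2_percent = co2_percent, o2_percent = o2_percent,
    cabp_ladder = cabp_ladder, read_interval = read_interval,
    duration = duration
  )
  class(x) <- "assay_constants"
  validate_assay_constants(x)
}

validate_assay_constants <- function(x) {
  stopifnot(inherits(x, "assay_constants"))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num1(x$epsilon340) || x$epsilon340 <= 0)
    stop("epsilon340 must be a positive number", call. = FALSE)
  if (!num1(x$path_length) || x$path_length <= 0)
    stop("path_length must be a positive number", call. = FALSE)
  if (!num1(x$nadh_per_carboxylation) || x$nadh_per_carboxylation <= 0)
    stop("nadh_per_carboxylation must be positive", call. = FALSE)
  if (!num1(x$nadh0) || x$nadh0 <= 0)
    stop("nadh0 must be positive (uM)", call. = FALSE)
  if (!num1(x$rubp_conc) || x$rubp_conc <= 0)
    stop("rubp_conc must be positive (mM)", call. = FALSE)
  if (!is.numeric(x$cabp_ladder) || length(x$cabp_ladder) == 0L ||
      anyNA(x$cabp_ladder) || any(x$cabp_ladder < 0))
    stop("cabp_ladder must be a non-empty vector of non-negative nM values",
         call. = FALSE)
  if (!num1(x$duration) || x$duration <= 0)
    stop("duration must be positive (s)", call. = FALSE)
  if (!num1(x$read_interval) || x$read_interval <= 0 ||
      x$read_interval > x$duration)
    stop("read_interval must be positive and not exceed duration",
         call. = FALSE)
  x
}

#' @export
print.assay_constants <- function(x, ...) {
  cat("NADH-coupled carboxylation assay constants\n")
  cat(sprintf("  epsilon340 x l : %g A/M (%g M^-1cm^-1 x %g cm)\n",
              x$epsilon340 * x$path_length, x$epsilon340, x$path_length))
  cat(sprintf("  NADH : %g uM initial, %g per carboxylation\n",
              x$nadh0, x$nadh_per_carboxylation))
  cat(sprintf("  RuBP : %g mM; %g degC; %g%% CO2 / %g%% O2\n",
              x$rubp_conc, x$temperature, x$co2_percent, x$o2_percent))
  cat(sprintf("  CABP ladder (nM): %s\n",
              paste(x$cabp_ladder, collapse = ", ")))
  cat(sprintf("  reads : every %g s for %g s\n", x$read_interval, x$duration))
  invisible(x)
}
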