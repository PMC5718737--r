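# TLD reading-to-dose reduction: background subtraction, per-chip
# sensitivity normalisation, calibration, decay-corrected effective
# exposure time, and quadrature uncertainty combination.

#' Raw TLD reading set
#'
#' One phantom exposure: per-chip raw reader outputs at known (r, theta)
#' positions, plus unexposed background chips and the exposure duration.
#'
#' @param chip_id Character or integer chip identifiers.
#' @param r,theta Chip positions: radius (cm) and polar angle (degrees).
#' @param reading Raw reader outputs (non-negative, reader units).
#' @param background_readings Raw readings of the background chips.
#' @param exposure_hours Exposure duration T in hours (> 0).
#' @param exposure_start Optional timestamp (POSIXct or character).
#' @return An object of class `tld_reading_set`.
#' @export
tld_reading_set <- function(chip_id, r, theta, reading, background_readings,
                            exposure_hours, exposure_start = NULL) {
  n <- length(chip_id)
  stopifnot(length(r) == n, length(theta) == n, length(reading) == n)
  if (any(reading < 0) || any(background_readings < 0))
    stop("raw readings must be >= 0", call. = FALSE)
  if (!is.numeric(exposure_hours) || exposure_hours <= 0)
    stop("exposure_hours must be > 0", call. = FALSE)
  structure(list(
    readings = data.frame(chip_id = as.character(chip_id), r = r,
                          theta = theta, reading = reading,
                          stringsAsFactors = FALSE),
    background_readings = as.numeric(background_readings),
    exposure_hours = exposure_hours,
    exposure_start = exposure_start), class = "tld_reading_set")
}

#' TLD calibration set
#'
#' Batch calibration metadata: the reader response per unit dose from a
#' Co-60 reference irradiation, per-chip relative sensitivity factors
#' (batch mean 1), an optional energy/position response correction, and
#' the type-B uncertainty components.
#'
#' @param epsilon_lambda Reader response per unit dose (reader units per
#'   cGy) for the calibration beam; positive.
#' @param sensitivity Named numeric vector of per-chip sensitivity
#'   factors; must be positive with batch mean 1 within 1e-6.
#' @param energy_response Optional correction E(r, theta): either a
#'   function of `(r, theta)` or a data frame with columns `r`, `theta`,
#'   `E` looked up by exact position. `NULL` means E = 1 everywhere.
#' @param type_b_components Optional data frame with columns `label` and
#'   `relative_pct` listing type-B uncertainty contributions.
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(epsilon_lambda, sensitivity,
                            energy_response = NULL,
                            type_b_components = NULL) {
  if (!is.numeric(epsilon_lambda) || epsilon_lambda <= 0)
    stop("epsilon_lambda must be > 0", call. = FALSE)
  if (any(sensitivity <= 0))
    stop("sensitivity factors must be > 0", call. = FALSE)
  if (abs(mean(sensitivity) - 1) > 1e-6)
    stop(sprintf("sensitivity factors must have batch mean 1 (got %.8f)",
                 mean(sensitivity)), call. = FALSE)
  if (is.null(names(sensitivity)))
    stop("sensitivity must be named by chip id", call. = FALSE)
  structure(list(epsilon_lambda = epsilon_lambda,
                 sensitivity = sensitivity,
                 energy_response = energy_response,
                 type_b_components = type_b_components),
            class = "calibration_set")
}

#' Per-chip sensitivity factors from a flat-field irradiation
#'
#' Before each experiment the whole chip batch receives the same dose
#' from a calibrated Co-60 beam; each chip's relative sensitivity is its
#' reading divided by the batch mean, so the factors average to exactly 1.
#'
#' @param co_irradiation_readings Named numeric vector (chip id ->
#'   reading) with at least two chips, all positive.
#' @return Named numeric vector of sensitivity factors.
#' @examples
#' sensitivity_factors(c(a = 90, b = 110))  # c(a = 0.9, b = 1.1)
#' @export
sensitivity_factors <- function(co_irradiation_readings) {
  x <- co_irradiation_readings
  if (length(x) < 2)
    stop("need at least 2 chips for sensitivity calibration", call. = FALSE)
  if (any(x <= 0))
    stop("calibration error: non-positive flat-field reading", call. = FALSE)
  x / mean(x)
}

#' Decay-corrected effective exposure time
#'
#' For a source decaying with constant lambda = ln(2) / T_half, a chip
#' exposed for T hours integrates `(1 - exp(-lambda T)) / lambda` hours'
#' worth of the initial dose rate. This is the standard decay correction:
#' it tends to T for exposures short against the half-life.
#'
#' @param T_hours Exposure duration in hours (> 0).
#' @param half_life_days Source half-life in days (> 0).
#' @return Effective exposure time in hours.
#' @examples
#' effective_exposure_time(1, 17)  # ~ 0.99915 h
#' @export
effective_exposure_time <- function(T_hours, half_life_days) {
  if (any(T_hours <= 0)) stop("T_hours must be > 0", call. = FALSE)
  if (any(half_life_days <= 0)) stop("half_life_days must be > 0", call. = FALSE)
  lambda <- log(2) / (half_life_days * 24)
  (1 - exp(-lambda * T_hours)) / lambda
}

.energy_response_at <- function(cal, r, theta) {
  er <- cal$energy_response
  if (is.null(er)) return(rep(1, length(r)))
  if (is.function(er)) return(er(r, theta))
  key <- paste(signif(r, 12), signif(theta, 12))
  tab <- stats::setNames(er$E, paste(signif(er$r, 12), signif(er$theta, 12)))
  out <- tab[key]
  if (anyNA(out))
    stop("calibration error: no energy-response entry for position (",
         r[which(is.na(out))[1]], ", ", theta[which(is.na(out))[1]], ")",
         call. = FALSE)
  unname(out)
}

#' Reduce raw TLD readings to dose rate per unit air-kerma strength
#'
#' The full reading-to-dose chain: subtract the mean background reading,
#' divide by the chip's sensitivity factor, then divide by the product of
#' effective exposure time, air-kerma strength, calibration response and
#' energy-response correction. Replicate chips at the same (r, theta) are
#' averaged.
#'
#' Two type-A dispersion measures are reported per position:
#' `type_a_pct`, the relative sample standard deviation of the replicate
#' chips (the k = 1 single-measurement dispersion), and
#' `type_a_mean_pct = type_a_pct / sqrt(n)`, the relative standard error
#' of the reported mean.
#'
#' Chips whose background-corrected reading is negative are clamped to
#' zero with a warning (chips near background at large distance are
#' expected), never an error.
#'
#' @param readings A [tld_reading_set()]; every chip id must have a
#'   sensitivity factor in `cal`.
#' @param cal A [calibration_set()].
#' @param sk Air-kerma strength of the source during exposure (U).
#' @param half_life_days Nuclide half-life (days); default the Pd-103
#'   value 16.991.
#' @return A data frame with one row per position: `r`, `theta`,
#'   `dose_per_sk` (cGy h^-1 U^-1), `type_a_pct`, `type_a_mean_pct`, `n`.
#' @export
reduce_tld <- function(readings, cal, sk, half_life_days = 16.991) {
  stopifnot(inherits(readings, "tld_reading_set"),
            inherits(cal, "calibration_set"))
  if (sk <= 0) stop("sk must be > 0", call. = FALSE)
  df <- readings$readings
  missing <- setdiff(df$chip_id, names(cal$sensitivity))
  if (length(missing))
    stop("calibration error: no sensitivity factor for chip(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  bkg <- mean(readings$background_readings)
  net <- df$reading - bkg
  if (any(net < 0)) {
    warning(sum(net < 0), " chip(s) below mean background; clamped to zero")
    net <- pmax(net, 0)
  }
  net <- net / cal$sensitivity[df$chip_id]
  t_eff <- effective_exposure_time(readings$exposure_hours, half_life_days)
  e_resp <- .energy_response_at(cal, df$r, df$theta)
  dose <- net / (t_eff * sk * cal$epsilon_lambda * e_resp)
  key <- paste(signif(df$r, 12), signif(df$theta, 12))
  agg <- lapply(split(seq_len(nrow(df)), key), function(i) {
    d <- dose[i]; m <- mean(d); n <- length(d)
    sd_pct <- if (n > 1 && m > 0) stats::sd(d) / m * 100 else NA_real_
    data.frame(r = df$r[i[1]], theta = df$theta[i[1]], dose_per_sk = m,
               type_a_pct = sd_pct, type_a_mean_pct = sd_pct / sqrt(n), n = n)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$r, out$theta), ]
  rownames(out) <- NULL
  out
}

#' Combine type-A and type-B uncertainties in quadrature
#'
#' The combined standard uncertainty is the square root of the sum of
#' the squares of the type-A (statistical) and type-B (systematic)
#' relative uncertainties.
#'
#' @param type_a,type_b Relative uncertainties in percent, both >= 0.
#' @return An object of class `uncertainty_budget` with fields `type_a`,
#'   `type_b`, `combined` (all relative percent).
#' @examples
#' combine_uncertainty(3, 4)$combined  # 5
#' @export
combine_uncertainty <- function(type_a, type_b) {
  if (any(c(type_a, type_b) < 0))
    stop("uncertainty components must be >= 0", call. = FALSE)
  structure(list(type_a = type_a, type_b = type_b,
                 combined = sqrt(type_a^2 + type_b^2)),
            class = "uncertainty_budget")
}
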