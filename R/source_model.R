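#' @keywords internal
"_PACKAGE"

# ---- domain types ----------------------------------------------------------

#' Cylindrical seed geometry
#'
#' Describes the physical construction of an encapsulated cylindrical
#' brachytherapy seed: a titanium (or other) capsule holding a column of
#' radioactive beads. All lengths are in centimetres.
#'
#' @param physical_length Overall capsule length (cm).
#' @param active_length Length of the radioactive column, the `L` of the
#'   line-source geometry function (cm).
#' @param capsule_outer_diameter,capsule_inner_diameter Capsule wall
#'   diameters (cm); the wall thickness is half their difference.
#' @param end_cap_thickness Thickness of each capsule end cap (cm).
#' @param bead_count Number of source beads.
#' @param bead_diameter Diameter of one bead (cm).
#' @param capsule_material Label, e.g. `"titanium"`.
#' @param core_material Label for the bead matrix, e.g. `"resin"`.
#' @param core_mass_fractions Named numeric vector of elemental mass
#'   fractions of the core material; must sum to 1.
#' @return An object of class `seed_geometry`.
#' @seealso [ir06_seed_geometry()] for the packaged Pd-103 seed.
#' @export
seed_geometry <- function(physical_length, active_length,
                          capsule_outer_diameter, capsule_inner_diameter,
                          end_cap_thickness, bead_count, bead_diameter,
                          capsule_material = "titanium",
                          core_material = "resin",
                          core_mass_fractions = NULL) {
  stopifnot(is.numeric(physical_length), is.numeric(active_length))
  if (active_length <= 0)
    stop("active_length must be > 0", call. = FALSE)
  if (active_length > physical_length)
    stop("active_length must not exceed physical_length", call. = FALSE)
  if (capsule_inner_diameter >= capsule_outer_diameter)
    stop("capsule_inner_diameter must be smaller than capsule_outer_diameter",
         call. = FALSE)
  if (!is.null(core_mass_fractions)) {
    if (abs(sum(core_mass_fractions) - 1) > 1e-9)
      stop("core_mass_fractions must sum to 1 (got ",
           format(sum(core_mass_fractions), digits = 12), ")", call. = FALSE)
  }
  structure(list(
    physical_length = physical_length,
    active_length = active_length,
    capsule_outer_diameter = capsule_outer_diameter,
    capsule_inner_diameter = capsule_inner_diameter,
    end_cap_thickness = end_cap_thickness,
    bead_count = as.integer(bead_count),
    bead_diameter = bead_diameter,
    capsule_material = capsule_material,
    core_material = core_material,
    core_mass_fractions = core_mass_fractions
  ), class = "seed_geometry")
}

#' Geometry of the packaged IR06 Pd-103 seed
#'
#' Five 0.6 mm resin beads in a 4.7 mm titanium capsule with 0.6 mm end
#' caps; the active column is 3 mm long. Core composition is the resin
#' bead matrix by mass fraction.
#'
#' @return A [seed_geometry()] object.
#' @export
ir06_seed_geometry <- function() {
  seed_geometry(
    physical_length = 0.47, active_length = 0.30,
    capsule_outer_diameter = 0.08, capsule_inner_diameter = 0.07,
    end_cap_thickness = 0.06, bead_count = 5L, bead_diameter = 0.06,
    capsule_material = "titanium", core_material = "resin",
    core_mass_fractions = c(H = 0.08, C = 0.90, N = 0.003,
                            Cl = 0.007, Pd = 0.01)
  )
}

#' Radionuclide description
#'
#' @param name Nuclide label, e.g. `"Pd-103"`.
#' @param half_life_days Half-life in days.
#' @param spectrum Optional data frame with columns `energy_kev` and
#'   `intensity` (photons per decay); not packaged, user-supplied.
#' @return An object of class `nuclide`.
#' @export
nuclide <- function(name, half_life_days, spectrum = NULL) {
  if (!is.numeric(half_life_days) || half_life_days <= 0)
    stop("half_life_days must be > 0", call. = FALSE)
  if (!is.null(spectrum)) {
    stopifnot(is.data.frame(spectrum),
              all(c("energy_kev", "intensity") %in% names(spectrum)))
    if (any(spectrum$intensity < 0))
      stop("spectrum intensities must be >= 0", call. = FALSE)
  }
  structure(list(name = name, half_life_days = half_life_days,
                 spectrum = spectrum), class = "nuclide")
}

#' Pd-103 nuclide with default half-life
#'
#' @param half_life_days Half-life in days; default 16.991 d.
#' @return A [nuclide()] object.
#' @export
pd103_nuclide <- function(half_life_days = 16.991) {
  nuclide("Pd-103", half_life_days)
}

#' Polar dose-rate grid
#'
#' Samples of dose rate on a polar lattice around a seed centred at the
#' origin with its long axis at theta = 0. Units are any consistent dose
#' rate (e.g. cGy/h, or per source history).
#'
#' @param radii Strictly increasing radii (cm), all positive.
#' @param angles Strictly increasing polar angles (degrees) in \[0, 360).
#' @param values Matrix of dose rates, `length(radii)` x `length(angles)`.
#' @param medium Label: `"water"`, `"perspex"`, `"vacuum"`, ...
#' @param uncertainty Optional matrix of relative 1-sigma values, same shape.
#' @return An object of class `dose_rate_grid`.
#' @export
dose_rate_grid <- function(radii, angles, values, medium = "water",
                           uncertainty = NULL) {
  grid <- structure(list(radii = as.numeric(radii),
                         angles = as.numeric(angles),
                         values = as.matrix(values),
                         medium = medium,
                         uncertainty = if (is.null(uncertainty)) NULL
                                       else as.matrix(uncertainty)),
                    class = "dose_rate_grid")
  bad <- validate_grid(grid)
  if (length(bad))
    stop("invalid dose_rate_grid:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  grid
}

#' Validate a polar dose-rate grid
#'
#' Checks every structural invariant of [dose_rate_grid()] and returns a
#' character vector describing each violation. Never raises; an empty
#' vector means the grid is valid.
#'
#' @param grid A `dose_rate_grid` (or a bare list with the same fields).
#' @return Character vector of violation descriptions (possibly empty).
#' @export
validate_grid <- function(grid) {
  out <- character()
  r <- grid$radii; a <- grid$angles; v <- grid$values
  if (!is.numeric(r) || length(r) < 1) out <- c(out, "radii missing or empty")
  else {
    if (any(r <= 0)) out <- c(out, "radii must all be > 0")
    if (length(r) > 1 && any(diff(r) <= 0)) out <- c(out, "radii not increasing")
  }
  if (!is.numeric(a) || length(a) < 1) out <- c(out, "angles missing or empty")
  else if (length(a) > 1 && any(diff(a) <= 0)) out <- c(out, "angles not increasing")
  if (is.null(v)) out <- c(out, "values missing")
  else {
    if (!identical(dim(v), c(length(r), length(a))))
      out <- c(out, sprintf("values shape %s does not match expected %d x %d",
                            paste(dim(v), collapse = " x "),
                            length(r), length(a)))
    neg <- which(v < 0, arr.ind = TRUE)
    if (nrow(neg))
      out <- c(out, sprintf("negative dose rate at cell (%d, %d)",
                            neg[1, 1], neg[1, 2]))
  }
  if (!is.null(grid$uncertainty) &&
      !identical(dim(grid$uncertainty), dim(v)))
    out <- c(out, "uncertainty shape does not match values")
  out
}

#' Vacuum ring-kerma profile
#'
#' Air-kerma rates scored in thin vacuum rings on the transverse axis at a
#' series of distances, used to estimate air-kerma strength.
#'
#' @param distances Strictly increasing distances (cm).
#' @param kerma_rates Kerma rates at those distances (dose unit per hour),
#'   all positive.
#' @param cutoff_delta Low-energy cutoff delta (keV) below which photons
#'   are excluded from the kerma definition; default 5 keV.
#' @return An object of class `ring_kerma_profile`.
#' @export
ring_kerma_profile <- function(distances, kerma_rates, cutoff_delta = 5) {
  distances <- as.numeric(distances); kerma_rates <- as.numeric(kerma_rates)
  if (length(distances) != length(kerma_rates))
    stop("distances and kerma_rates must have equal length", call. = FALSE)
  if (length(distances) > 1 && any(diff(distances) <= 0))
    stop("distances not increasing", call. = FALSE)
  if (any(kerma_rates <= 0))
    stop("kerma_rates must all be > 0", call. = FALSE)
  structure(list(distances = distances, kerma_rates = kerma_rates,
                 cutoff_delta = cutoff_delta), class = "ring_kerma_profile")
}

#' Radial dose function table
#'
#' Tabulated g(r): transverse-axis dose falloff relative to the reference
#' radius after the geometry function has been factored out.
#'
#' @param radii Radii (cm), strictly increasing.
#' @param g_values g(r) values, all positive.
#' @param geometry_model `"line"` or `"point"` — which geometry function
#'   was used in the extraction.
#' @param reference_radius Normalisation radius r0 (cm), default 1.
#' @return An object of class `radial_dose_table`.
#' @export
radial_dose_table <- function(radii, g_values, geometry_model = c("line", "point"),
                              reference_radius = 1) {
  geometry_model <- match.arg(geometry_model)
  radii <- as.numeric(radii); g_values <- as.numeric(g_values)
  if (length(radii) != length(g_values))
    stop("radii and g_values must have equal length", call. = FALSE)
  if (length(radii) > 1 && any(diff(radii) <= 0))
    stop("radii not increasing", call. = FALSE)
  if (any(g_values <= 0))
    stop("g_values must all be > 0", call. = FALSE)
  i0 <- which(abs(radii - reference_radius) < 1e-9)
  if (length(i0) == 1 && abs(g_values[i0] - 1) > 1e-12)
    stop(sprintf("g(r0 = %g) = %.15g, must equal 1 within 1e-12",
                 reference_radius, g_values[i0]), call. = FALSE)
  structure(list(radii = radii, g_values = g_values,
                 geometry_model = geometry_model,
                 reference_radius = reference_radius),
            class = "radial_dose_table")
}

#' 2D anisotropy function table
#'
#' Tabulated F(r, theta) on a polar lattice with angles in \[0, 90\]
#' degrees; the 90-degree column is the normalisation and must be exactly 1.
#'
#' @param radii Radii (cm), strictly increasing.
#' @param angles Angles (degrees) in \[0, 90\], strictly increasing.
#' @param F_values Matrix `length(radii)` x `length(angles)` of positive
#'   anisotropy values.
#' @return An object of class `anisotropy_table`.
#' @export
anisotropy_table <- function(radii, angles, F_values) {
  radii <- as.numeric(radii); angles <- as.numeric(angles)
  F_values <- as.matrix(F_values)
  if (length(radii) > 1 && any(diff(radii) <= 0))
    stop("radii not increasing", call. = FALSE)
  if (length(angles) > 1 && any(diff(angles) <= 0))
    stop("angles not increasing", call. = FALSE)
  if (any(angles < 0 | angles > 90))
    stop("angles must lie in [0, 90] degrees", call. = FALSE)
  if (!identical(dim(F_values), c(length(radii), length(angles))))
    stop("F_values shape does not match radii x angles", call. = FALSE)
  if (any(F_values <= 0))
    stop("F_values must all be > 0", call. = FALSE)
  i90 <- which(abs(angles - 90) < 1e-9)
  if (length(i90) == 1 && any(abs(F_values[, i90] - 1) > 1e-12))
    stop("F(r, 90 deg) must equal 1 within 1e-12 for every radius",
         call. = FALSE)
  structure(list(radii = radii, angles = angles, F_values = F_values),
            class = "anisotropy_table")
}

#' Consensus dosimetry dataset for one source model
#'
#' Bundles the dose-rate constants (experimental, Monte Carlo, and their
#' consensus average), the radial dose function table, the anisotropy
#' table, the seed geometry and the nuclide, with provenance labels.
#'
#' @param source_name Source model label.
#' @param lambda_exp,lambda_mc Experimental and Monte Carlo dose-rate
#'   constants (cGy h^-1 U^-1).
#' @param lambda_exp_sigma,lambda_mc_sigma Their 1-sigma uncertainties.
#' @param lambda_consensus Consensus dose-rate constant; must equal the
#'   mean of `lambda_exp` and `lambda_mc` within rounding of the stored
#'   precision (`consensus_tol`).
#' @param g_table A [radial_dose_table()].
#' @param F_table An [anisotropy_table()].
#' @param geometry A [seed_geometry()].
#' @param nuclide A [nuclide()].
#' @param medium Phantom medium label of the consensus value.
#' @param consensus_tol Absolute tolerance for the consensus invariant;
#'   default half a unit in the third decimal (the precision the constants
#'   are conventionally reported at).
#' @return An object of class `consensus_dataset`.
#' @export
consensus_dataset <- function(source_name, lambda_exp, lambda_mc,
                              lambda_consensus,
                              g_table, F_table, geometry, nuclide,
                              medium = "perspex",
                              lambda_exp_sigma = NA_real_,
                              lambda_mc_sigma = NA_real_,
                              consensus_tol = 5.000001e-4) {
  if (any(c(lambda_exp, lambda_mc, lambda_consensus) <= 0, na.rm = TRUE))
    stop("all dose-rate constants must be > 0", call. = FALSE)
  expect <- (lambda_exp + lambda_mc) / 2
  if (abs(lambda_consensus - expect) > consensus_tol)
    stop(sprintf(
      "lambda_consensus = %g is not the mean of lambda_exp and lambda_mc (%g)",
      lambda_consensus, expect), call. = FALSE)
  stopifnot(inherits(g_table, "radial_dose_table"),
            inherits(F_table, "anisotropy_table"),
            inherits(geometry, "seed_geometry"),
            inherits(nuclide, "nuclide"))
  structure(list(source_name = source_name,
                 lambda_exp = lambda_exp, lambda_exp_sigma = lambda_exp_sigma,
                 lambda_mc = lambda_mc, lambda_mc_sigma = lambda_mc_sigma,
                 lambda_consensus = lambda_consensus,
                 g_table = g_table, F_table = F_table,
                 geometry = geometry, nuclide = nuclide, medium = medium),
            class = "consensus_dataset")
}

# ---- structured-text dataset format ---------------------------------------

# Sections: [source], [lambda], [geometry], [nuclide], [g_table], [F_table].
# Key/value lines "key = value"; table blocks are CSV with a header row.
# "#" starts a comment. Numbers are written with %.17g so write/load
# round-trips are bit-identical.

.fmt_num <- function(x) sprintf("%.17g", x)

.parse_sections <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- NULL
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      sec <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[sec]] <- list(keys = list(), table = character())
    } else if (is.null(sec)) {
      stop("dataset format error: content before first [section]: ", ln,
           call. = FALSE)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[sec]]$keys[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    } else {
      out[[sec]]$table <- c(out[[sec]]$table, ln)
    }
  }
  out
}

.section_table <- function(sec, name) {
  if (length(sec$table) < 2)
    stop("dataset format error: section [", name, "] has no table rows",
         call. = FALSE)
  utils::read.csv(textConnection(paste(sec$table, collapse = "\n")),
                  strip.white = TRUE, check.names = FALSE)
}

.need_key <- function(sec, name, key) {
  v <- sec$keys[[key]]
  if (is.null(v))
    stop("dataset format error: missing field '", key, "' in [", name, "]",
         call. = FALSE)
  v
}

.num_key <- function(sec, name, key) {
  v <- suppressWarnings(as.numeric(.need_key(sec, name, key)))
  if (is.na(v))
    stop("dataset format error: field '", key, "' in [", name,
         "] is not numeric", call. = FALSE)
  v
}

#' Load a consensus dataset from its structured-text file
#'
#' Reads the package's human-diffable dataset format (sections `[source]`,
#' `[lambda]`, `[geometry]`, `[nuclide]`, `[g_table]`, `[F_table]`) and
#' re-validates every invariant, including g(r0) = 1 and F(., 90 deg) = 1.
#'
#' @param path Path to a dataset file; see
#'   `system.file("extdata", "ir06.tg43", package = "tg43seed")`.
#' @return A [consensus_dataset()].
#' @export
load_consensus_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  s <- .parse_sections(readLines(path, warn = FALSE))
  for (need in c("source", "lambda", "geometry", "nuclide",
                 "g_table", "F_table"))
    if (is.null(s[[need]]))
      stop("dataset format error: missing section [", need, "]",
           call. = FALSE)

  geo <- s$geometry
  frac_txt <- .need_key(geo, "geometry", "core_mass_fractions")
  fr <- strsplit(strsplit(frac_txt, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  fractions <- stats::setNames(vapply(fr, function(p) as.numeric(p[2]), 0),
                               vapply(fr, function(p) trimws(p[1]), ""))
  geometry <- seed_geometry(
    physical_length = .num_key(geo, "geometry", "physical_length"),
    active_length = .num_key(geo, "geometry", "active_length"),
    capsule_outer_diameter = .num_key(geo, "geometry", "capsule_outer_diameter"),
    capsule_inner_diameter = .num_key(geo, "geometry", "capsule_inner_diameter"),
    end_cap_thickness = .num_key(geo, "geometry", "end_cap_thickness"),
    bead_count = .num_key(geo, "geometry", "bead_count"),
    bead_diameter = .num_key(geo, "geometry", "bead_diameter"),
    capsule_material = .need_key(geo, "geometry", "capsule_material"),
    core_material = .need_key(geo, "geometry", "core_material"),
    core_mass_fractions = fractions)

  nuc <- nuclide(.need_key(s$nuclide, "nuclide", "name"),
                 .num_key(s$nuclide, "nuclide", "half_life_days"))

  gt <- .section_table(s$g_table, "g_table")
  if (!all(c("r_cm", "g") %in% names(gt)))
    stop("dataset format error: [g_table] needs columns r_cm, g",
         call. = FALSE)
  g_table <- radial_dose_table(
    gt$r_cm, gt$g,
    geometry_model = .need_key(s$g_table, "g_table", "geometry_model"),
    reference_radius = .num_key(s$g_table, "g_table", "reference_radius_cm"))

  ft <- .section_table(s$F_table, "F_table")
  if (names(ft)[1] != "r_cm" || !all(grepl("^theta_", names(ft)[-1])))
    stop("dataset format error: [F_table] needs columns r_cm, theta_<deg>",
         call. = FALSE)
  f_angles <- as.numeric(sub("^theta_", "", names(ft)[-1]))
  F_table <- anisotropy_table(ft$r_cm, f_angles,
                              as.matrix(ft[, -1, drop = FALSE]))

  consensus_dataset(
    source_name = .need_key(s$source, "source", "name"),
    medium = .need_key(s$source, "source", "medium"),
    lambda_exp = .num_key(s$lambda, "lambda", "exp"),
    lambda_exp_sigma = .num_key(s$lambda, "lambda", "exp_sigma"),
    lambda_mc = .num_key(s$lambda, "lambda", "mc"),
    lambda_mc_sigma = .num_key(s$lambda, "lambda", "mc_sigma"),
    lambda_consensus = .num_key(s$lambda, "lambda", "consensus"),
    g_table = g_table, F_table = F_table,
    geometry = geometry, nuclide = nuc)
}

#' Write a consensus dataset to the structured-text format
#'
#' Inverse of [load_consensus_dataset()]; numeric fields are written at
#' full double precision so a write/load round trip is bit-identical.
#'
#' @param dataset A [consensus_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_consensus_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "consensus_dataset"))
  g <- dataset$geometry
  fr <- paste(sprintf("%s:%s", names(g$core_mass_fractions),
                      .fmt_num(g$core_mass_fractions)), collapse = ",")
  gt <- dataset$g_table
  ft <- dataset$F_table
  lines <- c(
    "[source]",
    paste0("name = ", dataset$source_name),
    paste0("medium = ", dataset$medium),
    "",
    "[lambda]",
    "unit = cGy.h-1.U-1",
    paste0("exp = ", .fmt_num(dataset$lambda_exp)),
    paste0("exp_sigma = ", .fmt_num(dataset$lambda_exp_sigma)),
    paste0("mc = ", .fmt_num(dataset$lambda_mc)),
    paste0("mc_sigma = ", .fmt_num(dataset$lambda_mc_sigma)),
    paste0("consensus = ", .fmt_num(dataset$lambda_consensus)),
    "",
    "[geometry]",
    "unit = cm",
    paste0("physical_length = ", .fmt_num(g$physical_length)),
    paste0("active_length = ", .fmt_num(g$active_length)),
    paste0("capsule_outer_diameter = ", .fmt_num(g$capsule_outer_diameter)),
    paste0("capsule_inner_diameter = ", .fmt_num(g$capsule_inner_diameter)),
    paste0("end_cap_thickness = ", .fmt_num(g$end_cap_thickness)),
    paste0("bead_count = ", g$bead_count),
    paste0("bead_diameter = ", .fmt_num(g$bead_diameter)),
    paste0("capsule_material = ", g$capsule_material),
    paste0("core_material = ", g$core_material),
    paste0("core_mass_fractions = ", fr),
    "",
    "[nuclide]",
    paste0("name = ", dataset$nuclide$name),
    paste0("half_life_days = ", .fmt_num(dataset$nuclide$half_life_days)),
    "",
    "[g_table]",
    paste0("geometry_model = ", gt$geometry_model),
    paste0("reference_radius_cm = ", .fmt_num(gt$reference_radius)),
    "r_cm,g",
    sprintf("%s,%s", .fmt_num(gt$radii), .fmt_num(gt$g_values)),
    "",
    "[F_table]",
    paste(c("r_cm", sprintf("theta_%g", ft$angles)), collapse = ","),
    vapply(seq_along(ft$radii), function(i)
      paste(c(.fmt_num(ft$radii[i]), .fmt_num(ft$F_values[i, ])),
            collapse = ","), "")
  )
  writeLines(lines, path)
  invisible(path)
}

# ---- grid CSV interchange --------------------------------------------------

#' Read a polar dose-rate grid from CSV
#'
#' Expects a header `r_cm,theta_<deg>,...` with one row per radius, the
#' interchange layout used by all command-line tools in this package.
#'
#' @param path CSV file path.
#' @param medium Medium label to attach (not stored in the CSV).
#' @return A [dose_rate_grid()].
#' @export
read_grid_csv <- function(path, medium = "water") {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (names(df)[1] != "r_cm" || !all(grepl("^theta_", names(df)[-1])))
    stop("grid CSV must have columns r_cm, theta_<deg>", call. = FALSE)
  dose_rate_grid(df$r_cm, as.numeric(sub("^theta_", "", names(df)[-1])),
                 as.matrix(df[, -1, drop = FALSE]), medium = medium)
}

#' Write a polar dose-rate grid to CSV
#'
#' @param grid A [dose_rate_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  df <- data.frame(r_cm = grid$radii, grid$values, check.names = FALSE)
  names(df)[-1] <- sprintf("theta_%g", grid$angles)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- packaged fixtures -----------------------------------------------------

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "tg43seed")
  if (!nzchar(p)) stop("packaged fixture not found: ", file, call. = FALSE)
  p
}

#' The packaged IR06 Pd-103 consensus dataset
#'
#' Loads the shipped consensus dataset for the IR06 Pd-103 seed: consensus
#' dose-rate constant 0.690 cGy h^-1 U^-1 (mean of the TLD-measured and
#' Monte-Carlo Perspex values), the Perspex Monte Carlo radial dose
#' function, and the dense Monte Carlo anisotropy table.
#'
#' @return A [consensus_dataset()].
#' @export
ir06_dataset <- function() load_consensus_dataset(.extdata("ir06.tg43"))

#' Published radial dose function columns for the IR06 seed
#'
#' All three published g(r) determinations: Monte Carlo in Perspex, TLD
#' measurement in Perspex, and Monte Carlo in water, at the seven radii
#' 0.5--5 cm. The Perspex Monte Carlo column is the one the reference
#' fifth-order polynomial fit reproduces (see [fit_gl_polynomial()]).
#'
#' @return A data frame with columns `r_cm`, `g_perspex_mc`,
#'   `g_perspex_tld`, `g_water_mc`.
#' @export
ir06_radial_dose <- function() {
  utils::read.csv(.extdata("ir06_radial_dose.csv"), strip.white = TRUE)
}

#' Sparse TLD-measured anisotropy values for the IR06 seed
#'
#' The measured anisotropy points, kept separate from the dense Monte
#' Carlo table because the TLD phantom only supports angles
#' \{0, 30, 60\} degrees at radii \{1.5, 2, 3, 5\} cm.
#'
#' @return A data frame with columns `r_cm`, `theta_deg`, `F`.
#' @export
ir06_anisotropy_tld <- function() {
  utils::read.csv(.extdata("ir06_anisotropy_tld.csv"), strip.white = TRUE)
}

#' Published dose-rate-constant comparison table
#'
#' Dose-rate constants of the IR06 seed and three other commercial Pd-103
#' sources (Theragenics 200, MED3633, Best double-wall), by method and
#' medium, as packaged reference values for [build_comparison()].
#'
#' @return A data frame with columns `source`, `method`, `medium`,
#'   `lambda`, `sigma`, `reference`.
#' @export
lambda_comparison_table <- function() {
  utils::read.csv(.extdata("lambda_comparison.csv"), strip.white = TRUE)
}
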