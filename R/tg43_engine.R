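# TG-43U1 formalism: geometry functions, g(r)/F(r,theta) extraction,
# air-kerma strength, dose-rate constants, polynomial modelling, and
# forward dose-rate reconstruction.

.deg2rad <- function(deg) deg * pi / 180

# sin(theta) below this uses the axial limiting form 1/(r^2 - L^2/4);
# avoids catastrophic cancellation in beta/(L r sin theta).
.SIN_TOL <- 1e-6

#' Source geometry model for the geometry function
#'
#' @param kind `"line"` (uniform line source of length `L`) or `"point"`.
#' @param L Active length in cm; required for the line model.
#' @return An object of class `geometry_model`.
#' @export
geometry_model <- function(kind = c("line", "point"), L = NULL) {
  kind <- match.arg(kind)
  if (kind == "line") {
    if (is.null(L) || !is.numeric(L) || L <= 0)
      stop("line model requires L > 0", call. = FALSE)
  } else L <- NULL
  structure(list(kind = kind, L = L), class = "geometry_model")
}

#' TG-43 geometry function G(r, theta)
#'
#' Point model: `1/r^2`. Line model: `beta / (L r sin(theta))`, where
#' `beta` is the angle subtended by the active line at the calculation
#' point, computed from two-argument arctangents so obtuse geometries
#' (`r cos(theta) < L/2`) carry no branch errors. On the long axis
#' (`|sin(theta)|` below an internal tolerance) the continuous limiting
#' value `1/(r^2 - L^2/4)` is used.
#'
#' @param r Radius in cm (vectorised); must be positive, and for the line
#'   model greater than `L/2` (points inside the source extent are
#'   rejected).
#' @param theta Polar angle in degrees (vectorised; recycled against `r`).
#' @param model A [geometry_model()].
#' @return Geometry function values in cm^-2.
#' @examples
#' geometry_function(2, 90, geometry_model("point"))        # 0.25
#' geometry_function(1, 90, geometry_model("line", L = 0.3))
#' @export
geometry_function <- function(r, theta, model) {
  stopifnot(inherits(model, "geometry_model"))
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  if (model$kind == "point") return(1 / r^2 + 0 * theta)
  L <- model$L
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); th <- .deg2rad(rep_len(theta, n))
  s <- sin(th); z <- r * cos(th); y <- r * s
  axial <- abs(s) < .SIN_TOL
  if (any(axial & r <= L / 2))
    stop("r <= L/2 at an axial angle: point lies inside the source extent",
         call. = FALSE)
  out <- numeric(n)
  if (any(!axial)) {
    i <- !axial
    beta <- atan2(y[i], z[i] - L / 2) - atan2(y[i], z[i] + L / 2)
    out[i] <- beta / (L * y[i])
  }
  if (any(axial)) out[axial] <- 1 / (r[axial]^2 - L^2 / 4)
  out
}

.nearest_angle <- function(angles, target, tol) {
  i <- which.min(abs(angles - target))
  if (abs(angles[i] - target) > tol) return(NA_integer_)
  i
}

#' Extract the radial dose function g(r) from a dose-rate grid
#'
#' Applies the TG-43 definition
#' `g(r) = [D(r, 90) / D(r0, 90)] * [G(r0, 90) / G(r, 90)]`
#' to the transverse-axis column of a polar dose-rate grid. If `r0` is
#' not a grid radius the transverse dose rate there is obtained by linear
#' interpolation.
#'
#' @param grid A [dose_rate_grid()] containing a column at (or within
#'   `angular_tol` of) 90 degrees.
#' @param model A [geometry_model()].
#' @param r0 Reference radius in cm (default 1).
#' @param angular_tol Tolerance in degrees when locating the transverse
#'   column (default 0.5).
#' @return A [radial_dose_table()] with g(r0) = 1 exactly.
#' @export
extract_radial_dose <- function(grid, model, r0 = 1, angular_tol = 0.5) {
  stopifnot(inherits(grid, "dose_rate_grid"), inherits(model, "geometry_model"))
  i90 <- .nearest_angle(grid$angles, 90, angular_tol)
  if (is.na(i90))
    stop("grid has no angle column within ", angular_tol,
         " degrees of 90", call. = FALSE)
  d90 <- grid$values[, i90]
  if (r0 < min(grid$radii) || r0 > max(grid$radii))
    stop("r0 = ", r0, " outside grid radial range", call. = FALSE)
  d0 <- if (any(abs(grid$radii - r0) < 1e-9)) {
    d90[which.min(abs(grid$radii - r0))]
  } else {
    stats::approx(grid$radii, d90, xout = r0)$y
  }
  if (!is.finite(d0) || d0 <= 0)
    stop("degenerate input: dose rate at r0 is zero or undefined",
         call. = FALSE)
  g0 <- geometry_function(r0, 90, model)
  g <- (d90 / d0) * (g0 / geometry_function(grid$radii, 90, model))
  g[abs(grid$radii - r0) < 1e-9] <- 1
  radial_dose_table(grid$radii, g, geometry_model = model$kind,
                    reference_radius = r0)
}

#' Extract the 2D anisotropy function F(r, theta) from a dose-rate grid
#'
#' Applies the TG-43 definition
#' `F(r, theta) = [D(r, theta) / D(r, 90)] * [G(r, 90) / G(r, theta)]`
#' row by row. The 90-degree column is exactly 1 by construction. Grids
#' covering angles beyond 90 degrees must be folded onto the first
#' quadrant with [fold_angles()] first.
#'
#' @inheritParams extract_radial_dose
#' @return An [anisotropy_table()].
#' @export
extract_anisotropy <- function(grid, model, angular_tol = 0.5) {
  stopifnot(inherits(grid, "dose_rate_grid"), inherits(model, "geometry_model"))
  if (any(grid$angles > 90 + 1e-9))
    stop("grid has angles beyond 90 degrees; apply fold_angles() first",
         call. = FALSE)
  i90 <- .nearest_angle(grid$angles, 90, angular_tol)
  if (is.na(i90))
    stop("grid has no angle column within ", angular_tol,
         " degrees of 90", call. = FALSE)
  d90 <- grid$values[, i90]
  if (any(d90 <= 0))
    stop("degenerate input: zero dose rate on the transverse axis at r = ",
         grid$radii[which(d90 <= 0)[1]], call. = FALSE)
  Fm <- matrix(0, length(grid$radii), length(grid$angles))
  for (j in seq_along(grid$angles)) {
    gj <- geometry_function(grid$radii, grid$angles[j], model)
    g90 <- geometry_function(grid$radii, grid$angles[i90], model)
    Fm[, j] <- (grid$values[, j] / d90) * (g90 / gj)
  }
  Fm[, i90] <- 1
  anisotropy_table(grid$radii, grid$angles, Fm)
}

#' Fold a full-circle dose-rate grid onto the first quadrant
#'
#' Maps angles above 180 degrees to `360 - theta`, then angles above 90
#' to `180 - theta`, exploiting the cylindrical mirror symmetry of a
#' seed. Values landing on the same folded angle are averaged with equal
#' weights; relative uncertainties, when present, are combined as for an
#' equal-weight mean of independent samples.
#'
#' @param grid A [dose_rate_grid()] with angles in \[0, 360).
#' @return A [dose_rate_grid()] with angles in \[0, 90\].
#' @export
fold_angles <- function(grid) {
  stopifnot(inherits(grid, "dose_rate_grid"))
  a <- grid$angles
  if (any(a < 0 | a >= 360))
    stop("angles must lie in [0, 360)", call. = FALSE)
  folded <- ifelse(a > 180, 360 - a, a)
  folded <- ifelse(folded > 90, 180 - folded, folded)
  folded <- round(folded, 9)
  uniq <- sort(unique(folded))
  nv <- matrix(0, length(grid$radii), length(uniq))
  nu <- if (is.null(grid$uncertainty)) NULL else nv
  for (k in seq_along(uniq)) {
    j <- which(folded == uniq[k])
    nv[, k] <- rowMeans(grid$values[, j, drop = FALSE])
    if (!is.null(nu)) {
      # relative sigma of an equal-weight mean: sqrt(sum (sigma_i D_i)^2)/sum D_i
      abs_sd <- grid$uncertainty[, j, drop = FALSE] *
        grid$values[, j, drop = FALSE]
      nu[, k] <- sqrt(rowSums(abs_sd^2)) / pmax(rowSums(
        grid$values[, j, drop = FALSE]), .Machine$double.xmin)
    }
  }
  dose_rate_grid(grid$radii, uniq, nv, medium = grid$medium, uncertainty = nu)
}

#' Air-kerma strength from a vacuum ring-kerma profile
#'
#' Computes `K(r) * r^2` at each tabulated distance and returns the
#' unweighted mean as the air-kerma strength S_K (unit U = cGy cm^2 h^-1).
#' Because the profile is scored far from a finite-length source, the
#' per-distance estimates should be distance-independent; if their
#' maximum relative spread exceeds `tolerance` the result is flagged as
#' non-converged.
#'
#' @param profile A [ring_kerma_profile()] with at least two distances.
#' @param tolerance Maximum allowed relative spread
#'   `(max - min) / mean` of the per-distance estimates (default 0.01).
#' @return A list with elements `sk` (the mean), `estimates` (data frame
#'   `distance_cm`, `sk_estimate`), `converged` (logical) and
#'   `relative_spread`.
#' @export
air_kerma_strength <- function(profile, tolerance = 0.01) {
  stopifnot(inherits(profile, "ring_kerma_profile"))
  if (length(profile$distances) < 2)
    stop("ring-kerma profile needs at least 2 distances", call. = FALSE)
  est <- profile$kerma_rates * profile$distances^2
  spread <- (max(est) - min(est)) / mean(est)
  list(sk = mean(est),
       estimates = data.frame(distance_cm = profile$distances,
                              sk_estimate = est),
       converged = spread <= tolerance,
       relative_spread = spread)
}

#' Dose-rate constant
#'
#' The ratio of the dose rate to water at the reference point (1 cm on
#' the transverse axis) to the source's air-kerma strength.
#'
#' @param dose_at_ref Dose rate at (r0 = 1 cm, theta0 = 90 deg), cGy/h.
#' @param sk Air-kerma strength in U; must be positive.
#' @return Lambda in cGy h^-1 U^-1.
#' @export
dose_rate_constant <- function(dose_at_ref, sk) {
  if (any(sk <= 0)) stop("sk must be > 0", call. = FALSE)
  dose_at_ref / sk
}

#' Consensus dose-rate constant
#'
#' The recommended single value per source model: the arithmetic mean of
#' the experimentally measured and Monte-Carlo-calculated constants.
#'
#' @param lambda_exp,lambda_mc Positive dose-rate constants
#'   (cGy h^-1 U^-1).
#' @return Their mean.
#' @examples
#' consensus_lambda(0.689, 0.691)  # 0.690
#' @export
consensus_lambda <- function(lambda_exp, lambda_mc) {
  if (any(c(lambda_exp, lambda_mc) <= 0))
    stop("dose-rate constants must be > 0", call. = FALSE)
  (lambda_exp + lambda_mc) / 2
}

#' Polynomial model of the radial dose function
#'
#' Ordinary least-squares fit of g(r) as a polynomial in r,
#' `g(r) = a0 + a1 r + ... + a_d r^d` (default fifth order), over the
#' table's radial range. The coefficient of determination is
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about
#' the mean of the g values; for a constant table (SS_tot = 0) with a
#' perfect fit R^2 is reported as 1.
#'
#' @param table A [radial_dose_table()] with more points than `degree`.
#' @param degree Polynomial degree (default 5).
#' @return An object of class `polynomial_fit` with fields
#'   `coefficients` (a0..a_d), `r_range`, `degree` and `r_squared`.
#' @export
fit_gl_polynomial <- function(table, degree = 5L) {
  stopifnot(inherits(table, "radial_dose_table"))
  r <- table$radii; g <- table$g_values
  if (length(r) <= degree)
    stop("underdetermined fit: need more than ", degree, " points, got ",
         length(r), call. = FALSE)
  X <- outer(r, 0:degree, `^`)
  fit <- stats::lm.fit(X, g)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((g - mean(g))^2)
  r2 <- if (ss_tot < .Machine$double.eps) {
    if (ss_res < 1e-20) 1 else NA_real_
  } else 1 - ss_res / ss_tot
  structure(list(coefficients = stats::setNames(fit$coefficients,
                                                paste0("a", 0:degree)),
                 r_range = range(r), degree = as.integer(degree),
                 r_squared = r2),
            class = "polynomial_fit")
}

#' Evaluate a radial dose function
#'
#' For a [radial_dose_table()] this is piecewise-linear interpolation in
#' r, exact at tabulated radii; for a [fit_gl_polynomial()] result it is
#' polynomial evaluation. Requests outside the radial range raise an
#' error — there is no silent extrapolation.
#'
#' @param x A `radial_dose_table` or `polynomial_fit`.
#' @param r Radii (cm) at which to evaluate (vectorised).
#' @return g(r) values.
#' @export
evaluate_gl <- function(x, r) UseMethod("evaluate_gl")

#' @export
evaluate_gl.radial_dose_table <- function(x, r) {
  if (any(r < min(x$radii) - 1e-12 | r > max(x$radii) + 1e-12))
    stop("r outside tabulated range [", min(x$radii), ", ", max(x$radii),
         "]: extrapolation refused", call. = FALSE)
  stats::approx(x$radii, x$g_values, xout = r, rule = 1)$y
}

#' @export
evaluate_gl.polynomial_fit <- function(x, r) {
  if (any(r < x$r_range[1] - 1e-12 | r > x$r_range[2] + 1e-12))
    stop("r outside fitted range [", x$r_range[1], ", ", x$r_range[2],
         "]: extrapolation refused", call. = FALSE)
  drop(outer(r, 0:x$degree, `^`) %*% x$coefficients)
}

#' Evaluate the anisotropy function by bilinear interpolation
#'
#' Bilinear interpolation on the (r, theta) lattice of an
#' [anisotropy_table()]; exact at lattice nodes, and F(r, 90 deg) = 1 for
#' any in-range r because the normalisation column is identically 1.
#' Out-of-range requests raise an error.
#'
#' @param table An [anisotropy_table()].
#' @param r Radius (cm), vectorised.
#' @param theta Angle (degrees), vectorised (recycled against `r`).
#' @return F(r, theta) values.
#' @export
evaluate_f <- function(table, r, theta) {
  stopifnot(inherits(table, "anisotropy_table"))
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  R <- table$radii; A <- table$angles
  if (any(r < min(R) - 1e-12 | r > max(R) + 1e-12))
    stop("r outside tabulated range: extrapolation refused", call. = FALSE)
  if (any(theta < min(A) - 1e-12 | theta > max(A) + 1e-12))
    stop("theta outside tabulated range: extrapolation refused", call. = FALSE)
  ir <- pmin(pmax(findInterval(r, R), 1), length(R) - 1)
  ia <- pmin(pmax(findInterval(theta, A), 1), length(A) - 1)
  tr <- (r - R[ir]) / (R[ir + 1] - R[ir])
  ta <- (theta - A[ia]) / (A[ia + 1] - A[ia])
  tr <- pmin(pmax(tr, 0), 1); ta <- pmin(pmax(ta, 0), 1)
  v11 <- table$F_values[cbind(ir, ia)]
  v21 <- table$F_values[cbind(ir + 1, ia)]
  v12 <- table$F_values[cbind(ir, ia + 1)]
  v22 <- table$F_values[cbind(ir + 1, ia + 1)]
  (1 - tr) * (1 - ta) * v11 + tr * (1 - ta) * v21 +
    (1 - tr) * ta * v12 + tr * ta * v22
}

#' Forward TG-43 dose-rate reconstruction
#'
#' Evaluates the 2D dose-rate equation
#' `D(r, theta) = S_K * Lambda * [G(r, theta) / G(r0, theta0)] * g(r) * F(r, theta)`
#' with the line-source geometry model using the dataset's active length,
#' the reference point at (1 cm, 90 deg), linear interpolation of g and
#' bilinear interpolation of F.
#'
#' @param dataset A [consensus_dataset()].
#' @param sk Air-kerma strength in U; must be positive.
#' @param r Radius (cm), vectorised.
#' @param theta Polar angle (degrees), vectorised.
#' @return Dose rate in cGy/h.
#' @export
reconstruct_dose_rate <- function(dataset, sk, r, theta) {
  stopifnot(inherits(dataset, "consensus_dataset"))
  if (any(sk <= 0)) stop("sk must be > 0", call. = FALSE)
  model <- geometry_model("line", L = dataset$geometry$active_length)
  gref <- geometry_function(1, 90, model)
  sk * dataset$lambda_consensus *
    (geometry_function(r, theta, model) / gref) *
    evaluate_gl(dataset$g_table, r) *
    evaluate_f(dataset$F_table, r, theta)
}
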