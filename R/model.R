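# Volumes are held in cubic micrometres internally; unit densities are
# accepted and reported per cubic millimetre. 1 mm^3 = 1e9 um^3.
UM3_PER_MM3 <- 1e9

#' Dual observer model parameters
#'
#' The model triple: observation radius `r_obs` (micrometres) within which
#' a neuron's spikes can be sorted from one electrode; gain factor
#' `g = p_double / (2 p_single)` quantifying electrode cooperation in
#' doubly observed tissue (`g > 1` synergy, `g = 0.5` independence,
#' `g < 0.5` interference); and `p_single`, the density of sortable units
#' per cubic millimetre. The derived `p_double = 2 g p_single` is stored
#' alongside.
#'
#' @param r_obs Observation radius, micrometres (> 0).
#' @param g Gain factor (>= 0, dimensionless).
#' @param p_single Sortable-unit density per cubic millimetre (>= 0).
#' @return An object of class `dual_observer_params`.
#' @examples
#' dual_observer_params(r_obs = 42, g = 1.64, p_single = 2122)
#' @export
dual_observer_params <- function(r_obs, g, p_single = NA_real_) {
  if (r_obs <= 0) stop("r_obs must be positive", call. = FALSE)
  if (g < 0) stop("gain factor must be non-negative", call. = FALSE)
  if (!is.na(p_single) && p_single < 0) stop("p_single must be non-negative", call. = FALSE)
  structure(list(r_obs = r_obs, g = g, p_single = p_single,
                 p_double = 2 * g * p_single),
            class = "dual_observer_params")
}

#' @export
print.dual_observer_params <- function(x, ...) {
  cat("Dual observer parameters:\n")
  cat(sprintf("  R (observation radius): %g um\n", x$r_obs))
  cat(sprintf("  G (gain factor):        %g\n", x$g))
  cat(sprintf("  p_single:               %g / mm^3\n", x$p_single))
  invisible(x)
}

#' Expected unit yield of a configuration
#'
#' Expected number of well-isolated single units,
#' \eqn{N = p_{single}(V_{single} + 2 G V_{double})}: tissue seen by one
#' electrode contributes at density `p_single`, tissue seen by two or more
#' at `2 G p_single`.
#'
#' @param volumes A `volume_decomposition` (cubic micrometres).
#' @param params A `dual_observer_params` with finite `p_single`.
#' @return Expected unit count (dimensionless).
#' @export
unit_yield <- function(volumes, params) {
  stopifnot(inherits(volumes, "volume_decomposition"),
            inherits(params, "dual_observer_params"))
  if (is.na(params$p_single)) stop("p_single is required for unit yields", call. = FALSE)
  params$p_single *
    (volumes$v_single + 2 * params$g * volumes$v_double) / UM3_PER_MM3
}

#' Spike-sorting efficiency of a linear array
#'
#' Expected unit yield relative to the same number of independent
#' (non-interacting) electrodes, \eqn{E = N / (p_{single} M V_1)}. For a
#' linear equidistant array this is, with \eqn{V_2} the two-sphere lens
#' volume (zero for separated spheres),
#' \deqn{E = 1 + 2(G-1)\frac{M-1}{M}\frac{V_2(R,D)}{V_1(R)}
#'         - (2G-1)\frac{M-2}{M}\frac{V_2(R,2D)}{V_1(R)}.}
#' `E = 1` exactly for `d >= 2r` (no intersections, any `g`), and for
#' `g = 1` whenever `d >= r`. Vectorised over `d` and `g`.
#'
#' @param m Electrode count (>= 1).
#' @param r Observation radius, micrometres (> 0).
#' @param d Inter-electrode distance, micrometres (> 0).
#' @param g Gain factor.
#' @return Efficiency (dimensionless).
#' @examples
#' efficiency(32, r = 42, d = 48, g = 1.64)
#' @export
efficiency <- function(m, r, d, g) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  if (r <= 0) stop("r must be positive", call. = FALSE)
  if (any(d <= 0)) stop("d must be positive", call. = FALSE)
  v1 <- sphere_volume(r)
  c1 <- max(m - 1, 0) / m
  c2 <- max(m - 2, 0) / m
  1 + 2 * (g - 1) * c1 * lens_volume(r, d) / v1 -
    (2 * g - 1) * c2 * lens_volume(r, 2 * d) / v1
}

#' Expected units per channel of a linear array
#'
#' `unit_yield / m` for a linear equidistant configuration, the quantity
#' the model is fitted to.
#'
#' @inheritParams efficiency
#' @param p_single Sortable-unit density per cubic millimetre.
#' @return Expected units per channel.
#' @export
units_per_channel <- function(m, r, d, g, p_single) {
  params <- dual_observer_params(r, g, p_single)
  vapply(d, function(di) {
    unit_yield(linear_array_volumes(m, di, r), params) / m
  }, numeric(1))
}

#' Optimal inter-electrode distance
#'
#' Closed-form stationary point of the linear-array efficiency in the
#' second-neighbour overlap regime, valid for `m > 3`:
#' \deqn{D_{opt} = R \sqrt{\frac{4MG - 12G + 4}{7MG - 3M - 15G + 7}}.}
#' For `g <= 1` the efficiency has no interior maximum; tissue extent then
#' favours the densest spacing with non-overlapping-equivalent efficiency,
#' so the boundary value `d_opt = r` is returned with
#' `regime = "boundary_g_le_1"`. At `g = 1` the formula itself collapses to
#' `d_opt = r` exactly. As `g` and `m` grow large, `d_opt / r` approaches
#' `sqrt(4/7) ~ 0.76`.
#'
#' @param m Electrode count; the closed form requires `m > 3`.
#' @param r Observation radius, micrometres.
#' @param g Gain factor.
#' @param method `"closed_form"` (default) or `"search"`, a numeric
#'   maximisation of [efficiency()] over `d` for cases the closed form does
#'   not cover (e.g. `m <= 3`).
#' @return Optimal distance in micrometres, with attribute `regime` set to
#'   `"interior_optimum"` or `"boundary_g_le_1"`.
#' @examples
#' optimal_distance(32, r = 42, g = 1.64)  # ~36.75 um
#' @export
optimal_distance <- function(m, r, g, method = c("closed_form", "search")) {
  method <- match.arg(method)
  if (r <= 0) stop("r must be positive", call. = FALSE)
  if (g <= 1) {
    return(structure(r, regime = "boundary_g_le_1"))
  }
  if (method == "closed_form") {
    if (m <= 3) {
      stop("the closed form requires m > 3; use method = \"search\"",
           call. = FALSE)
    }
    num <- 4 * m * g - 12 * g + 4
    den <- 7 * m * g - 3 * m - 15 * g + 7
    return(structure(r * sqrt(num / den), regime = "interior_optimum"))
  }
  opt <- stats::optimize(function(d) efficiency(m, r, d, g),
                         interval = c(r * 1e-3, 2 * r), maximum = TRUE,
                         tol = r * 1e-10)
  structure(opt$maximum, regime = "interior_optimum")
}

#' Optimal efficiency of a linear array
#'
#' Two figures: the linear approximation `E_opt ~ 0.76 G + 0.16` for
#' `g > 1` (exactly 1 for `g <= 1`), which reproduces published summary
#' tables, and the exact efficiency evaluated at the closed-form optimum.
#'
#' @inheritParams optimal_distance
#' @return List with `e_opt_approx` and `e_opt_exact`.
#' @export
optimal_efficiency <- function(m, r, g) {
  approx <- if (g > 1) 0.76 * g + 0.16 else 1
  d_opt <- optimal_distance(m, r, g,
                            method = if (m > 3) "closed_form" else "search")
  list(e_opt_approx = approx,
       e_opt_exact = efficiency(m, r, as.numeric(d_opt), g))
}

#' Optimum summary for an electrode count
#'
#' Bundles the optimal distance, approximate and exact optimal efficiency,
#' and (when `p_single` is known) the optimal units per channel
#' `p_single * V_1(R) * E_opt_approx`. The approximate figure is the
#' published-table convention; the exact one evaluates the efficiency
#' formula at the optimum.
#'
#' @inheritParams optimal_distance
#' @param p_single Sortable-unit density per cubic millimetre (optional).
#' @return An object of class `optimum_result`: list with `m`, `d_opt`,
#'   `regime`, `e_opt_approx`, `e_opt_exact`, `opt_units_per_channel`.
#' @examples
#' optimal_config(32, r = 42, g = 1.64, p_single = 2122)
#' @export
optimal_config <- function(m, r, g, p_single = NA_real_) {
  d_opt <- optimal_distance(m, r, g,
                            method = if (m > 3) "closed_form" else "search")
  eff <- optimal_efficiency(m, r, g)
  upc <- if (is.na(p_single)) NA_real_ else {
    p_single * sphere_volume(r) / UM3_PER_MM3 * eff$e_opt_approx
  }
  structure(list(m = m, d_opt = as.numeric(d_opt),
                 regime = attr(d_opt, "regime"),
                 e_opt_approx = eff$e_opt_approx,
                 e_opt_exact = eff$e_opt_exact,
                 opt_units_per_channel = upc),
            class = "optimum_result")
}

#' @export
print.optimum_result <- function(x, ...) {
  cat(sprintf("Optimal configuration for M = %d electrodes:\n", x$m))
  d_str <- if (x$regime == "boundary_g_le_1") {
    sprintf(">= %.0f um (no interior optimum for G <= 1)", x$d_opt)
  } else {
    sprintf("%.0f um", x$d_opt)
  }
  cat("  optimal inter-electrode distance:", d_str, "\n")
  cat(sprintf("  optimal efficiency: %.2f (approx), %.4f (exact)\n",
              x$e_opt_approx, x$e_opt_exact))
  if (!is.na(x$opt_units_per_channel)) {
    cat(sprintf("  optimal units/channel: %.2f\n", x$opt_units_per_channel))
  }
  invisible(x)
}
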