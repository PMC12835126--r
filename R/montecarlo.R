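#' Monte-Carlo sampling settings
#'
#' Settings for the seeded Monte-Carlo volume estimator: number of uniform
#' sample points, RNG seed, and the margin by which the electrode bounding
#' box is expanded. The sampling box is the bounding box of the electrode
#' centres expanded by `max(margin, r)` along all three axes, so that every
#' observation sphere lies fully inside the box.
#'
#' @param n_points Number of uniform sample points (>= 1000; default 1e7).
#' @param seed Integer RNG seed.
#' @param margin Box margin in micrometres (default 200).
#' @return An object of class `mc_settings`.
#' @export
mc_settings <- function(n_points = 1e7, seed = 1L, margin = 200) {
  if (n_points < 1e3) stop("n_points must be at least 1000", call. = FALSE)
  if (margin < 0) stop("margin must be non-negative", call. = FALSE)
  structure(list(n_points = as.integer(n_points), seed = as.integer(seed),
                 margin = margin),
            class = "mc_settings")
}

# Cache of sorted nearest / second-nearest distance profiles, keyed by
# (layout coordinates, n_points, seed, effective margin). The fitting grid
# re-queries the same layout at hundreds of radii; the point cloud and the
# distance pass are shared across all of them.
.mc_cache <- new.env(parent = emptyenv())

#' Clear the Monte-Carlo profile cache
#' @return Invisibly, the number of entries dropped.
#' @export
mc_cache_clear <- function() {
  n <- length(ls(.mc_cache))
  rm(list = ls(.mc_cache), envir = .mc_cache)
  invisible(n)
}

mc_cache_key <- function(coords, settings, margin_eff) {
  paste(paste(signif(as.vector(coords), 12), collapse = ","),
        settings$n_points, settings$seed, signif(margin_eff, 12), sep = "|")
}

# Sorted d1/d2 profile for a layout: d1 = distance to the nearest
# electrode, d2 = to the second nearest, for every sample point.
mc_profile <- function(layout, settings, margin_eff, use_cache = TRUE) {
  coords <- layout_coords(layout)
  key <- mc_cache_key(coords, settings, margin_eff)
  if (use_cache && !is.null(.mc_cache[[key]])) return(.mc_cache[[key]])
  lo <- apply(coords, 2, min) - margin_eff
  hi <- apply(coords, 2, max) + margin_eff
  n <- settings$n_points
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(settings$seed)
  pts <- cbind(stats::runif(n, lo[1], hi[1]),
               stats::runif(n, lo[2], hi[2]),
               stats::runif(n, lo[3], hi[3]))
  dd <- nearest_two_dist(pts, coords)
  prof <- list(d1 = sort(dd[, 1]), d2 = sort.int(dd[, 2]),
               box_volume = prod(hi - lo), n = n)
  if (use_cache) .mc_cache[[key]] <- prof
  prof
}

mc_estimate <- function(prof, r) {
  n <- prof$n
  p1 <- findInterval(r, prof$d1) / n   # P(covered by >= 1 sphere)
  p2 <- findInterval(r, prof$d2) / n   # P(covered by >= 2 spheres)
  se <- function(p) prof$box_volume * sqrt(p * (1 - p) / n)
  list(v_total = prof$box_volume * p1,
       v_double = prof$box_volume * p2,
       se_total = se(p1), se_double = se(p2))
}

#' Monte-Carlo coverage volumes of an arbitrary layout
#'
#' Estimates the single/double-coverage decomposition of the observed
#' tissue volume by uniform rejection sampling: `n_points` points are drawn
#' in the expanded bounding box of the layout, each point is classified by
#' how many observation spheres of radius `r` cover it, and volumes follow
#' from the covered fractions. "Double" counts coverage by two *or more*
#' spheres. Deterministic given `(seed, n_points, layout, r)`. Binomial
#' standard errors are attached to the result.
#'
#' @param layout An `electrode_layout`.
#' @param r Observation radius, micrometres (>= 0).
#' @param settings An [mc_settings()] object.
#' @param use_cache Reuse the cached distance profile for repeated queries
#'   of the same layout/settings (default `TRUE`).
#' @return A `volume_decomposition` with `method = "monte_carlo"` and a
#'   `se` component (standard errors for `v_single`, `v_double`, `v_total`).
#' @export
mc_volumes <- function(layout, r, settings = mc_settings(), use_cache = TRUE) {
  if (r < 0) stop("observation radius must be non-negative", call. = FALSE)
  margin_eff <- max(settings$margin, r)
  prof <- mc_profile(layout, settings, margin_eff, use_cache = use_cache)
  est <- mc_estimate(prof, r)
  v_double <- est$v_double
  v_total <- est$v_total
  volume_decomposition(
    v_single = v_total - v_double, v_double = v_double, v_total = v_total,
    method = "monte_carlo",
    se = c(v_single = sqrt(est$se_total^2 + est$se_double^2),
           v_double = est$se_double, v_total = est$se_total)
  )
}

#' Coverage volumes at several radii from one point cloud
#'
#' Evaluates [mc_volumes()] at a vector of radii while sharing a single
#' sampled point cloud (box margin `max(margin, max(r))`), as used by the
#' grid-search fit. Much cheaper than independent calls and fully
#' deterministic given the seed.
#'
#' @inheritParams mc_volumes
#' @param r Vector of radii, micrometres.
#' @return Data frame with columns `r`, `v_single`, `v_double`, `v_total`,
#'   `se_double`, `se_total`.
#' @export
mc_volume_profile <- function(layout, r, settings = mc_settings(),
                              use_cache = TRUE) {
  if (any(r < 0)) stop("radii must be non-negative", call. = FALSE)
  margin_eff <- max(settings$margin, max(r))
  prof <- mc_profile(layout, settings, margin_eff, use_cache = use_cache)
  est <- mc_estimate(prof, r)
  data.frame(r = r,
             v_single = est$v_total - est$v_double,
             v_double = est$v_double,
             v_total = est$v_total,
             se_double = est$se_double,
             se_total = est$se_total)
}

#' Hybrid analytic / Monte-Carlo volume dispatch
#'
#' Chooses the cheapest exact route available: below the tangency limit
#' (`r <= pitch / 2`) no spheres intersect and the result is exactly
#' `m * V_1(r)` with zero double coverage; strictly linear equidistant
#' layouts use the exact inclusion-exclusion formulas; anything else (e.g.
#' zig-zag layouts with overlapping spheres) falls back to Monte-Carlo
#' estimation. The branch taken is recorded in the `method` field
#' (`"analytic_no_overlap"`, `"analytic_linear"`, or `"monte_carlo"`).
#'
#' @inheritParams mc_volumes
#' @return A `volume_decomposition`.
#' @export
hybrid_volumes <- function(layout, r, settings = mc_settings(),
                           use_cache = TRUE) {
  if (r < 0) stop("observation radius must be non-negative", call. = FALSE)
  m <- n_electrodes(layout)
  pitch <- layout_pitch(layout)
  if (m == 1 || (!is.na(pitch) && r <= pitch / 2)) {
    return(volume_decomposition(v_single = m * sphere_volume(r), v_double = 0,
                                method = "analytic_no_overlap"))
  }
  if (is_linear_equidistant(layout)) {
    out <- linear_array_volumes(m, pitch, r)
    out$method <- "analytic_linear"
    return(out)
  }
  mc_volumes(layout, r, settings, use_cache = use_cache)
}
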