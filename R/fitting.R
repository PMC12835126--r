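#' Units-per-channel yield dataset
#'
#' The fitting target: per-configuration, per-recording units-per-channel
#' observations, together with the electrode layout of every
#' configuration. Per-configuration medians (the quantity the model is
#' fitted to) are derived and ordered by pitch.
#'
#' @param observations Data frame with columns `config_label`,
#'   `recording_id`, `units_per_channel` (non-negative, finite).
#' @param layouts Named list of `electrode_layout` objects, one per
#'   distinct `config_label`.
#' @return An object of class `yield_data`: list with `observations`,
#'   `layouts`, and a derived `configs` data frame (`config_label`, `m`,
#'   `d_nn`, `n_recordings`, `median_upc`) ordered by increasing pitch.
#' @export
yield_data <- function(observations, layouts) {
  observations <- as.data.frame(observations)
  needed <- c("config_label", "recording_id", "units_per_channel")
  miss <- setdiff(needed, names(observations))
  if (length(miss)) {
    stop("observations lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v <- observations$units_per_channel
  if (any(!is.finite(v))) stop("units_per_channel contains non-finite values", call. = FALSE)
  if (any(v < 0)) stop("units_per_channel must be non-negative", call. = FALSE)
  labels <- unique(observations$config_label)
  miss_layout <- setdiff(labels, names(layouts))
  if (length(miss_layout)) {
    stop("no layout supplied for configuration(s): ",
         paste(miss_layout, collapse = ", "), call. = FALSE)
  }
  configs <- do.call(rbind, lapply(labels, function(lab) {
    lay <- layouts[[lab]]
    vals <- observations$units_per_channel[observations$config_label == lab]
    data.frame(config_label = lab, m = n_electrodes(lay),
               d_nn = layout_pitch(lay), n_recordings = length(vals),
               median_upc = stats::median(vals))
  }))
  configs <- configs[order(configs$d_nn), , drop = FALSE]
  rownames(configs) <- NULL
  structure(list(observations = observations, layouts = layouts[labels],
                 configs = configs),
            class = "yield_data")
}

#' @export
print.yield_data <- function(x, ...) {
  cat(sprintf("Units-per-channel dataset: %d configurations, %d observations\n",
              nrow(x$configs), nrow(x$observations)))
  print(x$configs, row.names = FALSE)
  invisible(x)
}

#' Read / write units-per-channel yields as CSV
#'
#' CSV dialect (UTF-8, header required): columns `config_label`,
#' `recording_id`, `n_channels`, `pitch_um`, and either `units_per_channel`
#' or the raw count `n_units` (divided by `n_channels` at ingest). When no
#' layout list is supplied, each configuration is assumed to be a linear
#' equidistant array of `n_channels` electrodes at `pitch_um` spacing.
#'
#' @param path CSV file path.
#' @param layouts Optional named list of `electrode_layout` objects keyed
#'   by `config_label`, overriding the linear-array assumption.
#' @return `read_yields` returns a `yield_data`; `write_yields` returns
#'   `path` invisibly.
#' @export
read_yields <- function(path, layouts = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("config_label", "recording_id", "n_channels", "pitch_um")
  miss <- setdiff(needed, names(df))
  if (!("units_per_channel" %in% names(df))) {
    if ("n_units" %in% names(df)) {
      df$units_per_channel <- df$n_units / df$n_channels
    } else {
      miss <- c(miss, "units_per_channel")
    }
  }
  if (length(miss)) {
    stop("yields CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  labels <- unique(df$config_label)
  lays <- lapply(labels, function(lab) {
    if (!is.null(layouts) && lab %in% names(layouts)) return(layouts[[lab]])
    row <- df[df$config_label == lab, ][1, ]
    linear_layout(row$n_channels, row$pitch_um, name = lab)
  })
  names(lays) <- labels
  yield_data(df[c("config_label", "recording_id", "units_per_channel")], lays)
}

#' @rdname read_yields
#' @param data A `yield_data` object.
#' @export
write_yields <- function(data, path) {
  obs <- data$observations
  cfg <- data$configs
  idx <- match(obs$config_label, cfg$config_label)
  out <- data.frame(config_label = obs$config_label,
                    recording_id = obs$recording_id,
                    n_channels = cfg$m[idx],
                    pitch_um = cfg$d_nn[idx],
                    units_per_channel = obs$units_per_channel)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Fitting grid specification
#'
#' The exhaustive search grid for the observation radius and gain factor.
#' Defaults: R from 1 to 200 micrometres in 1 micrometre steps, G from
#' 0.01 to 4 in steps of 0.01 (200 x 400 cells).
#'
#' @param r_min,r_max,r_step Radius range and step, micrometres.
#' @param g_min,g_max,g_step Gain-factor range and step.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(r_min = 1, r_max = 200, r_step = 1,
                      g_min = 0.01, g_max = 4, g_step = 0.01) {
  if (r_step <= 0 || g_step <= 0) stop("grid steps must be positive", call. = FALSE)
  if (r_min <= 0) stop("r_min must be positive", call. = FALSE)
  if (r_max < r_min || g_max < g_min) stop("grid ranges are empty", call. = FALSE)
  structure(list(r_min = r_min, r_max = r_max, r_step = r_step,
                 g_min = g_min, g_max = g_max, g_step = g_step),
            class = "grid_spec")
}

grid_r_values <- function(grid) {
  grid$r_min + grid$r_step * (0:floor((grid$r_max - grid$r_min) / grid$r_step + 1e-9))
}

grid_g_values <- function(grid) {
  grid$g_min + grid$g_step * (0:floor((grid$g_max - grid$g_min) / grid$g_step + 1e-9))
}

# Per-configuration coverage volumes along the radius grid, analytic
# wherever exact formulas apply and Monte-Carlo otherwise (one shared
# seeded point cloud per layout). Returns v_single / v_double matrices of
# size length(r) x n_configs plus the branch taken per configuration.
config_volume_profiles <- function(layouts, r_values, mc) {
  vs <- vd <- matrix(NA_real_, length(r_values), length(layouts))
  branch <- character(length(layouts))
  for (j in seq_along(layouts)) {
    lay <- layouts[[j]]
    m <- n_electrodes(lay)
    pitch <- layout_pitch(lay)
    if (m == 1) {
      vs[, j] <- sphere_volume(r_values); vd[, j] <- 0
      branch[j] <- "analytic_no_overlap"
    } else if (is_linear_equidistant(lay)) {
      v1 <- sphere_volume(r_values)
      v2a <- lens_volume(r_values, pitch)
      v2b <- lens_volume(r_values, 2 * pitch)
      vd[, j] <- max(m - 1, 0) * v2a - max(m - 2, 0) * v2b
      vs[, j] <- m * v1 - max(m - 1, 0) * v2a - vd[, j]
      branch[j] <- "analytic_linear"
    } else {
      prof <- mc_volume_profile(lay, r_values, mc)
      vs[, j] <- prof$v_single
      vd[, j] <- prof$v_double
      exact <- r_values <= pitch / 2   # hybrid rule: no intersections here
      vs[exact, j] <- m * sphere_volume(r_values[exact])
      vd[exact, j] <- 0
      branch[j] <- "monte_carlo"
    }
  }
  list(v_single = vs, v_double = vd, branch = branch)
}

#' Model-predicted units-per-channel pattern
#'
#' Predicted units per channel for each configuration at unit density
#' (`p_single` = 1 per cubic millimetre):
#' `(v_single_i + 2 g v_double_i) / m_i`, with volumes from the hybrid
#' analytic / Monte-Carlo route. The pattern scales linearly in `p_single`,
#' which is why the grid search can compare shapes only.
#'
#' @param r Observation radius, micrometres.
#' @param g Gain factor.
#' @param layouts List of `electrode_layout` objects.
#' @param mc An [mc_settings()] for non-linear layouts.
#' @return Numeric vector of units per channel at `p_single = 1`, in the
#'   order of `layouts`.
#' @export
predict_pattern <- function(r, g, layouts, mc = mc_settings()) {
  if (!length(layouts)) stop("no configurations supplied", call. = FALSE)
  prof <- config_volume_profiles(layouts, r, mc)
  m <- vapply(layouts, n_electrodes, numeric(1))
  drop((prof$v_single[1, ] + 2 * g * prof$v_double[1, ]) / (m * UM3_PER_MM3))
}

#' Fit the dual observer model to units-per-channel data
#'
#' Exhaustive grid search over (R, G): for every grid cell the predicted
#' units-per-channel pattern across the dataset's configurations is
#' compared with the observed per-configuration medians by cosine
#' similarity (amplitude-independent, so the comparison is insensitive to
#' `p_single`). The winning cell gives the radius and gain estimates; the
#' density estimate is the least-squares projection of the observed
#' medians onto the winning pattern, \eqn{\hat p = (y \cdot m)/(m \cdot m)}.
#' Ties on similarity resolve to the smallest radius, then the smallest
#' gain. Non-linear layouts use seeded Monte-Carlo volumes with one point
#' cloud shared across the whole radius grid, so the similarity surface is
#' free of sampling jitter and the fit is deterministic given the seed.
#'
#' @param data A [yield_data()] object with at least 3 configurations.
#' @param grid A [grid_spec()].
#' @param mc An [mc_settings()] used for non-linear layouts.
#' @param m_report Electrode count for the optimum summary (default 32).
#' @return An object of class `dual_observer_fit` with components
#'   `params` ([dual_observer_params()]), `similarity`, `predicted`
#'   (units/channel per configuration at the fitted density), `optimum`
#'   ([optimal_config()] at `m_report`), `data`, `grid`, `mc`, and
#'   `diagnostics` (grid argmax, ties, volume branches, seed).
#' @seealso [coef.dual_observer_fit()], [predict.dual_observer_fit()],
#'   [simulate.dual_observer_fit()], [fit_report()]
#' @examples
#' \donttest{
#' truth <- dual_observer_params(42, 1.64, 2122)
#' dat <- simulate_yields(truth, rodent_config_set(), n_recordings = 1,
#'                        noise = "none", mc = mc_settings(1e5, seed = 7))
#' fit <- fit_dual_observer(dat, mc = mc_settings(1e5, seed = 7))
#' coef(fit)
#' }
#' @export
fit_dual_observer <- function(data, grid = grid_spec(), mc = mc_settings(),
                              m_report = 32) {
  stopifnot(inherits(data, "yield_data"))
  cfg <- data$configs
  if (nrow(cfg) < 3) {
    stop("at least 3 distinct configurations are required to fit 3 parameters",
         call. = FALSE)
  }
  y <- cfg$median_upc
  if (all(y == 0)) {
    stop("all configuration medians are zero; cosine similarity is undefined",
         call. = FALSE)
  }
  layouts <- data$layouts[cfg$config_label]
  m <- cfg$m
  r_values <- grid_r_values(grid)
  g_values <- grid_g_values(grid)

  prof <- config_volume_profiles(layouts, r_values, mc)
  # pattern(r, g) = A(r) + g * B(r) per configuration (units/channel at
  # p_single = 1/mm^3); cosine similarity is then closed-form in g.
  A <- sweep(prof$v_single, 2, m * UM3_PER_MM3, "/")
  B <- sweep(2 * prof$v_double, 2, m * UM3_PER_MM3, "/")
  yA <- drop(A %*% y)
  yB <- drop(B %*% y)
  AA <- rowSums(A * A)
  AB <- rowSums(A * B)
  BB <- rowSums(B * B)
  num <- matrix(yA, length(r_values), length(g_values)) + yB %o% g_values
  den <- sqrt(matrix(AA, length(r_values), length(g_values)) +
                2 * (AB %o% g_values) + BB %o% (g_values^2))
  sim <- num / (den * sqrt(sum(y^2)))

  best <- max(sim)
  hits <- which(sim == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]  # min r, then min g
  r_hat <- r_values[hits[1, 1]]
  g_hat <- g_values[hits[1, 2]]
  pattern <- A[hits[1, 1], ] + g_hat * B[hits[1, 1], ]
  p_hat <- sum(y * pattern) / sum(pattern^2)

  params <- dual_observer_params(r_hat, g_hat, p_hat)
  structure(list(
    params = params,
    similarity = best,
    predicted = stats::setNames(p_hat * pattern, cfg$config_label),
    optimum = optimal_config(m_report, r_hat, g_hat, p_hat),
    data = data,
    grid = grid,
    mc = mc,
    diagnostics = list(
      argmax = c(r_index = unname(hits[1, 1]), g_index = unname(hits[1, 2])),
      n_ties = nrow(hits),
      grid_dim = c(n_r = length(r_values), n_g = length(g_values)),
      branches = stats::setNames(prof$branch, cfg$config_label),
      seed = mc$seed
    )
  ), class = "dual_observer_fit")
}

#' @export
print.dual_observer_fit <- function(x, ...) {
  cat("Dual observer model fit (grid search, cosine similarity)\n")
  cat(sprintf("  R = %g um, G = %g, p_single = %.4g / mm^3\n",
              x$params$r_obs, x$params$g, x$params$p_single))
  cat(sprintf("  cosine similarity: %.6f  (%d x %d grid%s)\n",
              x$similarity, x$diagnostics$grid_dim[["n_r"]],
              x$diagnostics$grid_dim[["n_g"]],
              if (x$diagnostics$n_ties > 1) {
                sprintf(", %d tied cells", x$diagnostics$n_ties)
              } else ""))
  invisible(x)
}

#' @export
coef.dual_observer_fit <- function(object, ...) {
  c(R_um = object$params$r_obs, G = object$params$g,
    p_single_per_mm3 = object$params$p_single)
}

#' @export
summary.dual_observer_fit <- function(object, ...) {
  print(object)
  cfg <- object$data$configs
  tab <- data.frame(config = cfg$config_label, m = cfg$m,
                    pitch_um = round(cfg$d_nn, 1),
                    observed = round(cfg$median_upc, 4),
                    predicted = round(unname(object$predicted), 4))
  cat("\nPer-configuration units/channel:\n")
  print(tab, row.names = FALSE)
  cat("\n")
  print(object$optimum)
  invisible(object)
}

#' Predict units per channel from a fitted model
#'
#' With `newdata = NULL`, returns the fitted per-configuration predictions.
#' `newdata` may be a data frame with columns `m` and `pitch_um` (linear
#' arrays) or a list of `electrode_layout` objects.
#'
#' @param object A `dual_observer_fit`.
#' @param newdata Optional configurations to predict for.
#' @param ... Unused.
#' @return Numeric vector of predicted units per channel.
#' @export
predict.dual_observer_fit <- function(object, newdata = NULL, ...) {
  p <- object$params
  if (is.null(newdata)) return(object$predicted)
  if (is.data.frame(newdata)) {
    stopifnot(all(c("m", "pitch_um") %in% names(newdata)))
    return(mapply(function(m, d) units_per_channel(m, p$r_obs, d, p$g, p$p_single),
                  newdata$m, newdata$pitch_um))
  }
  p$p_single * predict_pattern(p$r_obs, p$g, newdata, object$mc)
}

#' @export
residuals.dual_observer_fit <- function(object, ...) {
  object$data$configs$median_upc - unname(object$predicted)
}

#' Plot a fitted efficiency curve with the data
#'
#' Observed per-recording units per channel (open circles) and medians
#' (filled), against inter-electrode distance, with the fitted model curve
#' for a linear array of `m` electrodes.
#'
#' @param x A `dual_observer_fit`.
#' @param m Electrode count for the model curve (default: the optimum
#'   summary's count).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.dual_observer_fit <- function(x, m = x$optimum$m, ...) {
  cfg <- x$data$configs
  obs <- x$data$observations
  pitch <- cfg$d_nn[match(obs$config_label, cfg$config_label)]
  d_grid <- seq(min(cfg$d_nn) * 0.8, max(cfg$d_nn) * 1.1, length.out = 200)
  curve_upc <- units_per_channel(m, x$params$r_obs, d_grid, x$params$g,
                                 x$params$p_single)
  graphics::plot(pitch, obs$units_per_channel, log = "x",
                 xlab = "inter-electrode distance (um)",
                 ylab = "units per channel", col = "grey60", ...)
  graphics::lines(d_grid, curve_upc, lwd = 2)
  graphics::points(cfg$d_nn, cfg$median_upc, pch = 19)
  invisible(x)
}

#' Report table for a fitted model
#'
#' Summarises a fit the way published parameter tables do: fitted
#' parameters, and per requested electrode count the optimal
#' inter-electrode distance, optimal efficiency (approximate and exact)
#' and optimal units per channel; plus experimental comparators from the
#' dataset (best pitch used, units/channel of the densest configuration,
#' maximum achieved, and the improvement ratio optimal / densest). For
#' `G <= 1` the optimal distance is reported as `">= R um"` with a
#' boundary flag.
#'
#' @param fit A `dual_observer_fit`.
#' @param m_values Electrode counts to report optima for (default 32).
#' @return A list (class `fit_report`) serialisable to JSON with
#'   [write_fit_report()].
#' @export
fit_report <- function(fit, m_values = 32) {
  stopifnot(inherits(fit, "dual_observer_fit"))
  p <- fit$params
  cfg <- fit$data$configs
  per_m <- lapply(m_values, function(m) {
    opt <- optimal_config(m, p$r_obs, p$g, p$p_single)
    list(M = m,
         D_opt_um = opt$d_opt,
         D_opt_label = if (opt$regime == "boundary_g_le_1") {
           sprintf(">= %g um", p$r_obs)
         } else sprintf("%.0f um", opt$d_opt),
         E_opt_approx = opt$e_opt_approx,
         E_opt_exact = opt$e_opt_exact,
         opt_units_per_channel = opt$opt_units_per_channel,
         regime = opt$regime)
  })
  dense <- cfg[which.min(cfg$d_nn), ]
  best <- cfg[which.max(cfg$median_upc), ]
  experimental <- list(
    best_pitch_um = best$d_nn,
    high_density_units_per_channel = dense$median_upc,
    max_units_per_channel = max(cfg$median_upc),
    improvement_vs_high_density = vapply(per_m, function(x) {
      x$opt_units_per_channel / dense$median_upc
    }, numeric(1))
  )
  structure(list(
    params = list(R_um = p$r_obs, G = p$g, p_single_per_mm3 = p$p_single),
    similarity = fit$similarity,
    per_M = per_m,
    experimental = experimental,
    provenance = list(
      grid = unclass(fit$grid),
      seed = fit$mc$seed,
      version = as.character(utils::packageVersion("dualobserver"))
    )
  ), class = "fit_report")
}

#' @rdname fit_report
#' @param report A `fit_report`.
#' @param path Output JSON path.
#' @export
write_fit_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Dual observer fit report\n")
  cat(sprintf("  R = %g um, G = %g, p_single = %.4g / mm^3 (similarity %.4f)\n",
              x$params$R_um, x$params$G, x$params$p_single_per_mm3,
              x$similarity))
  for (row in x$per_M) {
    cat(sprintf("  M = %d: D_opt %s, E_opt %.2f (approx) / %.2f (exact), %.2f units/channel\n",
                row$M, row$D_opt_label, row$E_opt_approx, row$E_opt_exact,
                row$opt_units_per_channel))
  }
  cat(sprintf("  experimental: best pitch %.1f um, high-density %.2f u/ch, max %.2f u/ch\n",
              x$experimental$best_pitch_um,
              x$experimental$high_density_units_per_channel,
              x$experimental$max_units_per_channel))
  invisible(x)
}
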