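#' Simulate units-per-channel yield datasets
#'
#' Generates per-configuration, per-recording units-per-channel values with
#' the statistical structure the fitting pipeline assumes. For each
#' configuration the expected yield `N = p_single (V_single + 2 G V_double)`
#' is computed from the true parameters (hybrid analytic / Monte-Carlo
#' volumes), then per-recording values are drawn as either
#' * `"lognormal"`: `(N / M) * exp(e)`, `e ~ Normal(0, sigma^2)` —
#'   multiplicative recording-to-recording variability (default
#'   `sigma = 0.2`);
#' * `"poisson"`: `Poisson(N) / M` — integer count noise, appropriate when
#'   yields are small counts; or
#' * `"none"`: the noise-free expectation `N / M`.
#' Deterministic given `seed` (which is independent of the Monte-Carlo
#' volume seed in `mc`).
#'
#' @param params True `dual_observer_params` (with finite `p_single`).
#' @param layouts List of `electrode_layout` configurations.
#' @param n_recordings Recordings per configuration (default 6).
#' @param noise One of `"lognormal"`, `"poisson"`, `"none"`.
#' @param sigma Lognormal noise scale (standard deviation of `log` values).
#' @param seed Integer RNG seed for the noise draws.
#' @param mc [mc_settings()] for non-linear layout volumes.
#' @return A [yield_data()] object.
#' @examples
#' truth <- dual_observer_params(42, 1.64, 2122)
#' dat <- simulate_yields(truth, list(linear_layout(32, 48), linear_layout(64, 24),
#'                                    linear_layout(128, 12)),
#'                        n_recordings = 3, seed = 1)
#' @export
simulate_yields <- function(params, layouts, n_recordings = 6,
                            noise = c("lognormal", "poisson", "none"),
                            sigma = 0.2, seed = 1L, mc = mc_settings()) {
  noise <- match.arg(noise)
  stopifnot(inherits(params, "dual_observer_params"))
  if (n_recordings < 1) stop("n_recordings must be at least 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  labels <- vapply(layouts, function(l) l$name, character(1))
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }
  names(layouts) <- labels

  expected <- vapply(layouts, function(lay) {
    unit_yield(hybrid_volumes(lay, params$r_obs, mc), params)
  }, numeric(1))
  m <- vapply(layouts, n_electrodes, numeric(1))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  obs <- do.call(rbind, lapply(seq_along(layouts), function(j) {
    upc <- switch(noise,
      none = rep(expected[j] / m[j], n_recordings),
      lognormal = expected[j] / m[j] * exp(stats::rnorm(n_recordings, 0, sigma)),
      poisson = stats::rpois(n_recordings, expected[j]) / m[j]
    )
    data.frame(config_label = labels[j],
               recording_id = sprintf("rec%02d", seq_len(n_recordings)),
               units_per_channel = upc)
  }))
  yield_data(obs, layouts)
}

#' Simulate datasets from a fitted dual observer model
#'
#' Draws `nsim` replicate units-per-channel datasets at the fitted
#' parameters, over the configurations the model was fitted to. Parametric
#' simulation in the [stats::simulate()] sense; useful for parametric
#' bootstrap-style checks of the fitting pipeline.
#'
#' @param object A `dual_observer_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed; replicate `i` uses `seed + i - 1`.
#' @param n_recordings Recordings per configuration (default: the median
#'   recording count of the fitted dataset).
#' @param noise,sigma Noise model, as in [simulate_yields()].
#' @param ... Unused.
#' @return A list of `yield_data` objects of length `nsim`.
#' @export
simulate.dual_observer_fit <- function(object, nsim = 1, seed = 1L,
                                       n_recordings = NULL,
                                       noise = "lognormal", sigma = 0.2, ...) {
  if (is.null(n_recordings)) {
    n_recordings <- round(stats::median(object$data$configs$n_recordings))
  }
  layouts <- object$data$layouts[object$data$configs$config_label]
  lapply(seq_len(nsim), function(i) {
    simulate_yields(object$params, layouts, n_recordings = n_recordings,
                    noise = noise, sigma = sigma, seed = seed + i - 1L,
                    mc = object$mc)
  })
}
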