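# Independent oracles, kept free of the package's own volume code paths.

# Exact-by-quadrature coverage volumes for collinear equal spheres.
# The union of spheres centred on an axis is rotationally symmetric, so at
# axial coordinate t the cross-section covered by sphere i is a disc of
# squared radius s_i(t) = r^2 - (t - c_i)^2 (when positive). The area
# covered by >= 1 sphere is pi * max_i s_i^+, by >= 2 spheres
# pi * secondmax_i s_i^+; integrating along the axis gives the volumes.
axial_volumes_oracle <- function(m, d, r, n_grid = 40001) {
  centers <- (seq_len(m) - 1) * d
  t <- seq(-r, centers[m] + r, length.out = n_grid)
  S <- pmax(r^2 - outer(t, centers, "-")^2, 0)
  top2 <- apply(S, 1, function(x) sort(x, decreasing = TRUE)[1:2])
  if (m == 1) top2 <- rbind(top2, 0)
  area1 <- pi * top2[1, ]
  area2 <- pi * top2[2, ]
  dt <- diff(t[1:2])
  trap <- function(a) dt * (sum(a) - (a[1] + a[length(a)]) / 2)
  v_total <- trap(area1)
  v_double <- trap(area2)
  list(v_total = v_total, v_double = v_double, v_single = v_total - v_double)
}

# Dense-grid argmax of the efficiency curve, the brute-force oracle for
# the closed-form optimal distance.
brute_force_d_opt <- function(m, r, g, step = r / 2000) {
  d_grid <- seq(step, 2 * r, by = step)
  e <- efficiency(m, r, d_grid, g)
  d_grid[which.max(e)]
}

make_temp_yields_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
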