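# Shared fixtures: parameter bundles are cheap to build but reused widely.
fast_solver <- solver_config(rtol = 1e-8, atol = 1e-10, dt_out = 0.02)
coarse_solver <- solver_config(rtol = 1e-6, atol = 1e-8, dt_out = 0.05)

man_bpa <- default_pbk_params("BPA", "man")
rat_bpaf <- default_pbk_params("BPAF", "rat")

# brute-force SSE grid search, independent oracle for the kinetic fits
grid_search_mm <- function(pairs, vmax_grid, km_grid) {
  best <- list(sse = Inf)
  for (vm in vmax_grid) for (km in km_grid) {
    sse <- sum((pairs$v - vm * pairs$s / (km + pairs$s))^2)
    if (sse < best$sse) best <- list(sse = sse, vmax = vm, km = km)
  }
  best
}
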