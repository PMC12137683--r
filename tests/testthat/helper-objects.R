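# shared fixtures: built in code, kept small so the full suite stays fast
water37 <- water_properties(37)
geom_default <- well_geometry()

# coarse solver configuration for tests that only need qualitative fields
cfg_coarse <- solver_config(n_cells = 100, spinup_periods = 2,
                            record_rate = 500)

profile_740 <- make_motion_profile(motion_settings(7, 40))

# a hand-constructed shear map for analysis-only tests
fake_shear_map <- function(speeds, row_peaks, row_avgs = row_peaks / 2,
                           n_pos = 5) {
  structure(list(
    speeds = speeds, x = seq(-0.03, 0.03, length.out = n_pos),
    avg = matrix(rep(row_avgs, n_pos), ncol = n_pos),
    peak = matrix(rep(row_peaks, n_pos), ncol = n_pos),
    failed = rep(FALSE, length(speeds)),
    fill_volume = 5e-6, max_angle = 7, fluid = water37,
    config = cfg_coarse), class = "shear_map")
}
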