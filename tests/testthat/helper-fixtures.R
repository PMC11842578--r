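# shared fixtures built in code

ref_ctran <- matrix(c(-0.025, 0.111, -0.086,
                      -0.143, 0.274, -0.131), nrow = 2, byrow = TRUE)
ref_aaxi <- c(-0.167, 0.109, -0.094, 0.382)

# a hand-built ramp-and-drop trace: baseline, linear rise to `peak`,
# collapse to `after` within `collapse` samples, then flat
ramp_drop_trace <- function(peak = 3.9, n_pre = 50, n_rise = 100,
                            collapse = 5, n_post = 200, after = 0.1,
                            rate = 1000) {
  total <- c(rep(0, n_pre),
             seq(0, peak, length.out = n_rise),
             seq(peak, after, length.out = collapse + 1)[-1],
             rep(after, n_post))
  n <- length(total)
  force_trace(seq(0, by = 1 / rate, length.out = n),
              fx = total, fy = rep(0, n), fz = rep(0, n),
              rupture_index = n_pre + n_rise)
}

# small configuration for fast end-to-end cycles in tests
fast_config <- function(...) {
  sim_config(
    sample_rate = 250,
    transport = list(start_um = 0, target_um = 1000, tol_um = 5,
                     max_t_s = 6),
    ...
  )
}
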