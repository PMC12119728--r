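# Shared fixtures, built in code at test time.

# The 28-frame dynamic acquisition scheme (10x15 s, 3x60 s, 5x120 s,
# 9x300 s, 1x360 s).
make_schedule28 <- function() {
  frame_schedule_from_counts(c(10, 3, 5, 9, 1), c(15, 60, 120, 300, 360))
}

make_input28 <- function() {
  make_population_aif(schedule = make_schedule28())
}

# Reference lesion kinetics used across the kinetic tests.
lesion_truth <- function(vb = 0.03) {
  list(k1 = 0.1, k2 = 0.15, k3 = 0.02, vb = vb)
}
ki_macro_true <- 0.1 * 0.02 / (0.15 + 0.02)

# Voxel-radius field on an odd cubic grid, centre voxel at (c,c,c).
radius_field <- function(n = 41L) {
  ctr <- (n + 1L) / 2
  ax <- (seq_len(n) - ctr)^2
  sqrt(outer(outer(ax, ax, "+"), ax, "+"))
}

# DCE plasma curve on a uniform grid (minutes): gamma-variate first pass
# plus a washout tail, arriving near 1 min.
make_dce_cp <- function(t) {
  5 * gamma_variate(t * 60, t0 = 55, alpha = 3, beta = 6) +
    2.5 * pmin(pmax(t - 55 / 60, 0) / 0.5, 1) * exp(-0.08 * t)
}
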