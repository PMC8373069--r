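# Independent oracles used to freeze expected values. These never call the
# implementation paths they check.

# naive double-loop time-averaged MSD
msd_oracle <- function(x, max_lag = length(x) - 1L) {
  N <- length(x)
  vapply(seq_len(max_lag), function(n) {
    s <- 0
    for (i in seq_len(N - n)) s <- s + (x[i + n] - x[i])^2
    s / (N - n)
  }, numeric(1))
}

# empirical complementary CDF (survival with no censoring)
ccdf_oracle <- function(t, durations) {
  vapply(t, function(ti) mean(durations > ti), numeric(1))
}

# bound DNA from mass action, solved numerically (not in closed form)
bound_dna_oracle <- function(E, S, kd) {
  f <- function(B) (E - B) * (S - B) - kd * B
  stats::uniroot(f, c(0, min(E, S)), tol = 1e-14)$root
}

# straight-line OLS through the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# uniform-grid trajectory helper
make_traj <- function(x, dt = 1, id = "p", channel = "605") {
  trajectory(id, (seq_along(x) - 1) * dt, x, channel = channel)
}

# motile Brownian/fBm track from the generator internals, in um
make_motile_track <- function(n_frames, D, alpha, dt = 1 / 12.5,
                              noise_sd = 0, id = "p") {
  path <- sqrt(2 * D) *
    tightropekit:::sample_displacement(n_frames - 1L, alpha, dt)
  if (noise_sd > 0) path <- path + stats::rnorm(n_frames, sd = noise_sd)
  make_traj(path, dt = dt, id = id)
}
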