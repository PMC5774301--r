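# Shared fixtures, built in code.

equidistant_times <- function() seq(3, 30, by = 0.5)

clean_sigmoidal_tc <- function(I_max = 5, t_mid = 14, a1 = 1) {
  t <- equidistant_times()
  time_course(t, sigmoidal_value(t, sigmoidal_params(I_max, t_mid, a1)))
}

clean_double_tc <- function(I_max = 5, I_final = 1, t_mid1 = 10,
                            t_mid2 = 20, a1 = 2, a2 = 1) {
  t <- equidistant_times()
  p <- double_sigmoidal_params(I_max, I_final, t_mid1, t_mid2, a1, a2)
  list(tc = time_course(t, double_sigmoidal_value(t, p)), params = p)
}

# Count sign changes of successive differences on a dense grid; equals
# the number of interior local extrema of a piecewise-monotone function.
# Differences below a relative tolerance are treated as flat so that
# float rounding on saturated plateaus does not masquerade as extrema.
# The analytic maximizer must agree with a brute-force grid argmax:
# either in location (within 1.5 grid steps) or, for numerically flat
# maxima where the grid argmax is ill-conditioned, in achieved value.
tstar_matches_grid <- function(p, n_grid = 20001) {
  lo <- p$t_mid1_prime - 20 / p$a1_prime
  hi <- p$t_mid2_prime + 20 / p$a2_prime
  g <- seq(lo, hi, length.out = n_grid)
  v <- dsig_base_value(g, p$a1_prime, p$a2_prime,
                       p$t_mid1_prime, p$t_mid2_prime)
  ts <- find_tstar(p)
  v_ts <- dsig_base_value(ts, p$a1_prime, p$a2_prime,
                          p$t_mid1_prime, p$t_mid2_prime)
  abs(ts - g[which.max(v)]) < (hi - lo) / (n_grid - 1) * 1.5 ||
    v_ts >= max(v) * (1 - 1e-12)
}

grid_sign_changes <- function(values, rel_tol = 1e-9) {
  d <- diff(values)
  d[abs(d) <= rel_tol * max(abs(values))] <- 0
  s <- sign(d)
  s <- s[s != 0]
  sum(diff(s) != 0)
}
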