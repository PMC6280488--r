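# shared fixtures: parameter sets of the published trial fits and small
# simulation helpers used across test files

table2_sets <- list(
  misoprostol_miso = c(5.58, 0.71, -8.60),
  misoprostol_oxy = c(5.46, 0.69, -12.01),
  am_simplified = c(5.63, 0.63, -47.38),
  am_full = c(5.57, 0.65, -43.53),
  champion = c(5.19, 0.83, -22.25),
  althabe_hands_off = c(5.57, 0.72, 55.14),
  althabe_cct = c(5.37, 0.80, 62.88))

params_of <- function(x) lognormal_params(x[1], x[2], x[3])

# positive volumes from the threshold-lognormal law (rejection of v <= 0,
# the blood-loss measurement process)
draw_positive <- function(n, params, seed) {
  set.seed(seed)
  v <- numeric(0)
  while (length(v) < n) {
    x <- rlnorm3(2 * n, params)
    v <- c(v, x[x > 0])
  }
  v[seq_len(n)]
}
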