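# Reference mouse configuration used across the suite.
ref_growth <- function() growth_params()
ref_pk <- function() pk_params()
ref_regimen <- function() {
  make_regimen(dosage = 5, weight = 0.025,
               days = c(1, 4, 8, 11, 15, 18, 22, 25, 29), duration = 1 / 48)
}
# Twice-weekly sampling over a month, the cadence of the xenograft
# experiments the synthetic generator emulates.
twice_weekly <- function(from = 0, to = 31.5) seq(from, to, by = 3.5)

# Hand-built trajectory for endpoint-function tests.
toy_trajectory <- function(time, V, K = V, I = 0) {
  vascgro:::new_trajectory(
    data.frame(time = time, V = V, K = K, I = rep(I, length.out = length(time))),
    v_star = pi / 6)
}
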