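# Shared fixtures: the bistable reference parameter set and its exit domain.
p_ref <- tfa_params(6, 10, 1, 0.4)
x_minus <- 0.62685
x_u <- 1.48971
x_plus <- 4.28343
D_ref <- domain1d(0, x_u)

# second parameter set (deeper left well)
p_alt <- tfa_params(7.5, 10, 1, 0.1)

# parameters so small that the drift is numerically zero / linear
p_null <- tfa_params(1e-12, 10, 1e-12, 1e-12)       # f ~ 0
p_linear <- tfa_params(1e-9, 10, 1, 0.4)            # f ~ -x + 0.4

# two-sided Kolmogorov-Smirnov distance of a sample to a cdf
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n))
}

# fixed seed used throughout: the package default documented in load_config
seed_default <- 20160714
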