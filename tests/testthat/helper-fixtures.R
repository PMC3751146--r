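# Small fixtures built in code.

# Random strictly-positive differential DVH on a uniform grid.
random_dvh <- function(n = 50, bin_width = 0.5, seed = 7, unit = "Gy") {
  withr::with_seed(seed, {
    v <- runif(n, 0.1, 1)
    dvh_differential((seq_len(n) - 0.5) * bin_width, v / sum(v),
                     "random", unit, bin_width = bin_width)
  })
}

# Uniform whole-organ irradiation at a single dose.
uniform_dvh <- function(dose, unit = "Gy", bin_width = 0.05) {
  dvh_differential(dose, 1, "uniform", unit, bin_width = bin_width)
}

hodgkin_params <- function() rs_params(d50 = 70.3, gamma = 0.96, s = 1)
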