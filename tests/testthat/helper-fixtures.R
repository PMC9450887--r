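# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# A clean Lorentzian profile on a 40-point S-phase grid.
lorentzian_profile <- function(noise_sd = 0, seed = NULL,
                               par = c(B = 0.1, A = 1, t0 = 300,
                                       gamma = 120)) {
  sim_profile("lorentzian", par, times = seq(0, 585, by = 15),
              noise_sd = noise_sd, seed = seed)
}

# Matched-width generator parameters for the four-model repertoire: all
# produce a pulse with baseline 0.1, peak ~1.1 and FWHM ~240 s on [0, 585].
repertoire_params <- function() {
  list(
    lorentzian = c(B = 0.1, A = 1, t0 = 300, gamma = 120),
    gaussian = c(B = 0.1, A = 1, t0 = 300, sigma = 240 / 2.355),
    inc_const_dec = c(y0 = 0.1, m1 = 1 / 200, m2 = -1 / 200, t1 = 200,
                      t2 = 400),
    inc_dec = c(y0 = 0.1, m1 = 1 / 300, m2 = -1 / 300, t_b = 300)
  )
}

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Small noiseless cohort for exactness tests.
clean_cohort <- function(n_embryos = 3, seed = 1, ...) {
  sim_embryo_cohort(
    cohort_spec(n_embryos = n_embryos, centrioles_per_embryo = 5,
                bleach_tau = Inf, background_level = 0,
                centriole_scatter_cv = 0, noise_sd = 0,
                peak_time_sd = 0, ...),
    seed = seed)
}
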