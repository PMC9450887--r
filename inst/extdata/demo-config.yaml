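# Demo configuration: small end-to-end synthetic run.
# Any omitted entry falls back to the package defaults.
seed: 1
out_dir: "centriodyn-out"
stages: [simulate, ringfit, dynamics, correlate, growth, pecos]
simulate:
  rings:
    n_rings: 12
    radius_range: [100, 250]
    ecc_range: [1.0, 1.4]
    w: 40
    psf_sigma: 60
    noise: gaussian
    noise_sd: 0.05
    write_images: false
  cohort:
    n_embryos: 10
    centrioles_per_embryo: 20
  growth:
    n_profiles: 10
    rate: 0.0333
    period: 300
    noise_sd: 0.05
  pecos:
    n_controls: 4
    n_samples: 8
    bin_width: 0.005
    background_rate: 50
    transit_rate: 0.2
ringfit:
  ecc_max: 1.2
dynamics:
  model: auto
  scale_max1: true
pecos:
  q: 0.01
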