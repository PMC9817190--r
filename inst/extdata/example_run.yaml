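# Example run configuration for quadpop::run_pipeline().
# Generates a synthetic 20-quadrat survey (seeded, hence reproducible) and
# analyses the dominant shrub. Replace `generator` with `stems:`/`herbs:`
# CSV paths to analyse field data instead.
design:
  n_quadrats: 20
  quadrat_area: 25
  n_subquadrats: 3
  subquadrat_area: 1
generator:
  seed: 12
  species:
    - name: Cydonia oblonga
      expected_density: 4000
      bd_model: {type: truncated_exponential, rate: 0.35, max_bd: 16}
      height_model: [0.35, 0.2, 0.2]
    - name: Spiraea chinensis
      expected_density: 2500
      bd_model: {type: truncated_exponential, rate: 1.3, max_bd: 4}
    - name: Carex brunnea
      layer: herb
      presence_prob: 0.85
      abundance_mean: 8
      coverage_model: [19, 5]
      height_mean: 0.21
species: Cydonia oblonga
radix: 1000
h: 1
horizons: [2, 4, 6, 8]
coverage_mode: crown_ellipse
overflow: clamp
outdir: quadpop_report
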