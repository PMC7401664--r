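# Default trait architecture for the simulated Warmblood breeding program.
# Heritabilities and phenotypic standard deviations per recording event,
# OCD liability traits and height at withers, published genetic/residual
# correlations, and the fill rules for correlation entries without a
# literature estimate. Prevalences of the two OCD traits and sigma_p of
# height are package assumptions (configurable here).
traits:
  - {key: fs_type,         name: type,         event: foal_show,    kind: continuous, h2: 0.50, sigma_p: 0.79}
  - {key: fs_exterior,     name: exterior,     event: foal_show,    kind: continuous, h2: 0.50, sigma_p: 0.62}
  - {key: fs_movement,     name: movement,     event: foal_show,    kind: continuous, h2: 0.41, sigma_p: 0.87}
  - {key: sb_walk,         name: walk,         event: studbook,     kind: continuous, h2: 0.25, sigma_p: 0.80}
  - {key: sb_trot,         name: trot,         event: studbook,     kind: continuous, h2: 0.42, sigma_p: 0.88}
  - {key: sb_canter,       name: canter,       event: studbook,     kind: continuous, h2: 0.49, sigma_p: 0.71}
  - {key: mt_walk,         name: walk,         event: mare_test,    kind: continuous, h2: 0.26, sigma_p: 0.79}
  - {key: mt_trot,         name: trot,         event: mare_test,    kind: continuous, h2: 0.40, sigma_p: 0.76}
  - {key: mt_canter,       name: canter,       event: mare_test,    kind: continuous, h2: 0.36, sigma_p: 0.71}
  - {key: mt_rideability,  name: rideability,  event: mare_test,    kind: continuous, h2: 0.28, sigma_p: 0.73}
  - {key: mt_freejump,     name: free_jumping, event: mare_test,    kind: continuous, h2: 0.36, sigma_p: 0.92}
  - {key: d14_walk,        name: walk,         event: test_14day,   kind: continuous, h2: 0.41, sigma_p: 0.81}
  - {key: d14_trot,        name: trot,         event: test_14day,   kind: continuous, h2: 0.71, sigma_p: 0.74}
  - {key: d14_canter,      name: canter,       event: test_14day,   kind: continuous, h2: 0.56, sigma_p: 0.60}
  - {key: d14_rideability, name: rideability,  event: test_14day,   kind: continuous, h2: 0.50, sigma_p: 0.65}
  - {key: d14_freejump,    name: free_jumping, event: test_14day,   kind: continuous, h2: 0.74, sigma_p: 0.71}
  - {key: d50_walk,        name: walk,         event: test_50day,   kind: continuous, h2: 0.33, sigma_p: 0.80}
  - {key: d50_trot,        name: trot,         event: test_50day,   kind: continuous, h2: 0.47, sigma_p: 0.85}
  - {key: d50_canter,      name: canter,       event: test_50day,   kind: continuous, h2: 0.42, sigma_p: 0.74}
  - {key: d50_rideability, name: rideability,  event: test_50day,   kind: continuous, h2: 0.36, sigma_p: 0.89}
  - {key: d50_freejump,    name: free_jumping, event: test_50day,   kind: continuous, h2: 0.47, sigma_p: 0.99}
  - {key: d50_coursejump,  name: course_jumping, event: test_50day, kind: continuous, h2: 0.40, sigma_p: 1.12}
  - {key: ocd_fj,          name: ocd_fj,       event: health,       kind: binary,     h2: 0.189, sigma_p: 1.0, prevalence: 0.25}
  - {key: ocd_hj,          name: ocd_hj,       event: health,       kind: binary,     h2: 0.369, sigma_p: 1.0, prevalence: 0.10}
  - {key: height,          name: height,       event: conformation, kind: continuous, h2: 0.275, sigma_p: 2.0, mean: 166.5}
# published pairwise correlations (by trait key)
known_genetic_correlations:
  - [ocd_fj, ocd_hj, -0.27]
  - [ocd_fj, height,  0.349]
  - [ocd_hj, height,  0.181]
known_residual_correlations:
  - [ocd_fj, ocd_hj, 0.085]
  - [ocd_fj, height, 0.037]
  - [ocd_hj, height, 0.119]
# genetic correlations between OCD and performance traits, applied to the
# trait of that name at every recording event
ocd_genetic_correlations_by_name:
  walk:         {ocd_fj: -0.01, ocd_hj: -0.11}
  trot:         {ocd_fj: -0.04, ocd_hj: -0.06}
  canter:       {ocd_fj:  0.08, ocd_hj: -0.09}
  rideability:  {ocd_fj: -0.03, ocd_hj: -0.06}
  free_jumping: {ocd_fj: -0.09, ocd_hj:  0.01}
# fill rules for entries without a literature estimate
defaults:
  same_trait_rg: 0.85     # same trait name recorded at different events
  within_event_rg: 0.40   # different performance traits at the same event
  cross_event_rg: 0.34    # different performance traits at different events
  within_event_re: 0.20
  cross_event_re: 0.0
  unknown_ocd_rg: 0.0     # OCD vs traits with no published estimate
  height_performance_rg: 0.0
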