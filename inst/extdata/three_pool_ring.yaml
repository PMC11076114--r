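# Three pools in a directed ring, one two-site lane per edge.
# With total_particles = 4 the steady state is
# [0.09514 0.04541 0.8249 0.9082 0.1998 0.0908 0.12613 0.5745 1.1350].
pools: [P1, P2, P3]
chains:
  - id: R1
    n_sites: 2
    rates: [0.8, 1.0, 2.0]
    source_pool: P1
    sink_pool: P2
    input_function: {name: tanh}
  - id: R2
    n_sites: 2
    rates: [1.0, 1.2, 0.1]
    source_pool: P2
    sink_pool: P3
    input_function: {name: tanh}
  - id: R3
    n_sites: 2
    rates: [0.1, 0.5, 1.0]
    source_pool: P3
    sink_pool: P1
    input_function: {name: identity}
initial_state: [0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.0, 0.0, 1.0]
total_particles: 4
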