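# Minimal two-pool network: one lane each way, two sites per lane.
# Pool I feeds X1 through G(z) = tanh(z); pool II feeds Y1 through
# H(z) = z. With total_particles = 2 the steady state is
# [0.3589 0.2302 0.1909 0.2763 0.6023 0.3414].
pools: [I, II]
chains:
  - id: X1
    n_sites: 2
    rates: [0.8, 1.0, 1.2]
    source_pool: I
    sink_pool: II
    input_function: {name: tanh}
  - id: Y1
    n_sites: 2
    rates: [1.0, 2.0, 1.0]
    source_pool: II
    sink_pool: I
    input_function: {name: identity}
initial_state: [0.5, 0.5, 0.5, 0.5, 0.0, 0.0]
total_particles: 2
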