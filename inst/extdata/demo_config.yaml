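# Demo pipeline configuration: a small statewide simulation.
simulation:
  n_patients: 4000
  seed: 20090101
seed: 7
percent_digits: 1
network_year: 2018
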