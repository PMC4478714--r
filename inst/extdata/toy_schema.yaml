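# Minimal schema config for a two-variable fusion toy example.
# Categorical variables declare their labels and optional raw-file code
# aliases (surveys often store 1='Female', 2='Male').
variables:
  - name: gender
    role: common
    kind: categorical
    levels: [Female, Male]
    codes: {"1": Female, "2": Male}
  - name: age
    role: common
    kind: continuous
    units: years
  - name: score
    role: specific
    kind: continuous
  - name: grade
    role: specific
    kind: categorical
    levels: [low, high]
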