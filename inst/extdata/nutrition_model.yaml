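# Four-latent recursive chain: community-practice factor -> food factor ->
# service factor -> toddler nutritional status, all blocks reflective.
blocks:
  X:
    - X1.1
  Y1:
    - Y1.1
    - Y1.2
  Y2:
    - Y2.1
    - Y2.2
    - Y2.3
    - Y2.4
  Y3:
    - Y3.1
    - Y3.2
    - Y3.3
modes:
  X: reflective
  Y1: reflective
  Y2: reflective
  Y3: reflective
paths:
  - X -> Y1
  - Y1 -> Y2
  - Y2 -> Y3
scheme: centroid
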