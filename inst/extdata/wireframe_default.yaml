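# Default wireframe edge set over the default schema: face outline, mouth
# polygon, eye and olfactory connectors, neuromast verticals.
name: default
edges:
  # face outline
  - [1, 2]
  - [2, 10]
  - [10, 24]
  - [24, 26]
  - [26, 25]
  - [25, 11]
  - [11, 3]
  - [3, 1]
  # mouth polygon
  - [16, 18]
  - [18, 20]
  - [20, 22]
  - [22, 23]
  - [23, 21]
  - [21, 19]
  - [19, 17]
  - [17, 16]
  # eyes
  - [6, 8]
  - [7, 9]
  # olfactory placodes to glabella
  - [1, 4]
  - [1, 5]
  # neuromast verticals
  - [12, 14]
  - [13, 15]
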