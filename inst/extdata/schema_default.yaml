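# Default rostral-view facial landmark schema: 26 landmarks, 4 on the midline
# and 11 bilateral pairs. Names parallel human anthropometry where a homologue
# exists (labiale superius/inferius, chelion, crista philtri). Sides are as
# seen in the rostral image (viewer's left/right); coordinates follow the
# ImageJ convention (origin top-left, y increases downward).
name: default
landmarks:
  - {index: 1,  name: "glabella",              side: midline}
  - {index: 2,  name: "frontotemporale L",     side: left,  pair: 3}
  - {index: 3,  name: "frontotemporale R",     side: right, pair: 2}
  - {index: 4,  name: "olfactory placode L",   side: left,  pair: 5}
  - {index: 5,  name: "olfactory placode R",   side: right, pair: 4}
  - {index: 6,  name: "eye medial canthus L",  side: left,  pair: 7}
  - {index: 7,  name: "eye medial canthus R",  side: right, pair: 6}
  - {index: 8,  name: "eye lateral canthus L", side: left,  pair: 9}
  - {index: 9,  name: "eye lateral canthus R", side: right, pair: 8}
  - {index: 10, name: "zygion L",              side: left,  pair: 11}
  - {index: 11, name: "zygion R",              side: right, pair: 10}
  - {index: 12, name: "neuromast superior L",  side: left,  pair: 13}
  - {index: 13, name: "neuromast superior R",  side: right, pair: 12}
  - {index: 14, name: "neuromast inferior L",  side: left,  pair: 15}
  - {index: 15, name: "neuromast inferior R",  side: right, pair: 14}
  - {index: 16, name: "labiale superius",      side: midline}
  - {index: 17, name: "crista philtri L",      side: left,  pair: 18}
  - {index: 18, name: "crista philtri R",      side: right, pair: 17}
  - {index: 19, name: "chelion L",             side: left,  pair: 20}
  - {index: 20, name: "chelion R",             side: right, pair: 19}
  - {index: 21, name: "oral lateral L",        side: left,  pair: 22}
  - {index: 22, name: "oral lateral R",        side: right, pair: 21}
  - {index: 23, name: "labiale inferius",      side: midline}
  - {index: 24, name: "gonion L",              side: left,  pair: 25}
  - {index: 25, name: "gonion R",              side: right, pair: 24}
  - {index: 26, name: "gnathion",              side: midline}
# Mouth landmarks (indices 16-23, 8 of 26) carry roughly one third of the
# schema, giving the oral cavity finer resolution than the rest of the face.
mouth_indices: [16, 17, 18, 19, 20, 21, 22, 23]
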