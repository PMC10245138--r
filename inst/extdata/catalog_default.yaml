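# Default facial measurement catalog: 39 automated measurements (distances,
# angles, areas and composites) over the default 26-landmark schema.
# Angle definitions list the vertex landmark second. `provenance: named`
# marks measurements whose names are taken directly from published usage;
# `provenance: reconstructed` marks mirrored counterparts and composites
# added to complete the catalog where the source naming is not explicit.
name: default
version: "1.0"
features:
  # --- linear distances ---
  - {name: facial_width,              kind: distance, landmarks: [10, 11], provenance: named}
  - {name: facial_height,             kind: distance, landmarks: [1, 26],  provenance: named}
  - {name: midface_width,             kind: distance, landmarks: [2, 3],   provenance: reconstructed}
  - {name: mouth_width,               kind: distance, landmarks: [19, 20], provenance: named}
  - {name: mouth_height,              kind: distance, landmarks: [16, 23], provenance: named}
  - {name: upper_lip_width,           kind: distance, landmarks: [17, 18], provenance: named}
  - {name: lower_mouth_width,         kind: distance, landmarks: [21, 22], provenance: reconstructed}
  - {name: chin_width,                kind: distance, landmarks: [24, 25], provenance: named}
  - {name: jaw_height,                kind: distance, landmarks: [23, 26], provenance: reconstructed}
  - {name: midface_height,            kind: distance, landmarks: [1, 16],  provenance: reconstructed}
  - {name: olfactory_distance,        kind: distance, landmarks: [4, 5],   provenance: named}
  - {name: olfactory_to_chin_L,       kind: distance, landmarks: [4, 26],  provenance: reconstructed}
  - {name: olfactory_to_chin_R,       kind: distance, landmarks: [5, 26],  provenance: reconstructed}
  - {name: olfactory_to_mouth_L,      kind: distance, landmarks: [4, 19],  provenance: reconstructed}
  - {name: olfactory_to_mouth_R,      kind: distance, landmarks: [5, 20],  provenance: reconstructed}
  - {name: interocular_distance,      kind: distance, landmarks: [6, 7],   provenance: reconstructed}
  - {name: outer_canthal_distance,    kind: distance, landmarks: [8, 9],   provenance: reconstructed}
  - {name: eye_width_L,               kind: distance, landmarks: [6, 8],   provenance: reconstructed}
  - {name: eye_width_R,               kind: distance, landmarks: [7, 9],   provenance: reconstructed}
  - {name: neuromast_width,           kind: distance, landmarks: [14, 15], provenance: named}
  - {name: neuromast_height_L,        kind: distance, landmarks: [12, 14], provenance: reconstructed}
  - {name: neuromast_height_R,        kind: distance, landmarks: [13, 15], provenance: reconstructed}
  # --- angles (vertex listed second) ---
  - {name: labiale_superius_angle,    kind: angle, landmarks: [17, 16, 18], provenance: named}
  - {name: labiale_inferius_angle,    kind: angle, landmarks: [19, 23, 20], provenance: named}
  - {name: crista_philtri_angle_L,    kind: angle, landmarks: [16, 17, 19], provenance: named}
  - {name: crista_philtri_angle_R,    kind: angle, landmarks: [16, 18, 20], provenance: named}
  - {name: chelion_angle_L,           kind: angle, landmarks: [16, 19, 23], provenance: named}
  - {name: chelion_angle_R,           kind: angle, landmarks: [16, 20, 23], provenance: named}
  - {name: olfactory_mouth_angle_L,   kind: angle, landmarks: [1, 4, 19],   provenance: reconstructed}
  - {name: olfactory_mouth_angle_R,   kind: angle, landmarks: [1, 5, 20],   provenance: reconstructed}
  # --- areas ---
  - {name: mouth_area, kind: polygon_area, landmarks: [16, 18, 20, 22, 23, 21, 19, 17], provenance: named}
  - {name: area_top,    kind: polygon_area, landmarks: [1, 11, 10],  provenance: named}
  - {name: area_bottom, kind: polygon_area, landmarks: [10, 11, 26], provenance: reconstructed}
  # --- composites ---
  - {name: facial_area_combined,             kind: composite, op: sum,
     inputs: [area_top, area_bottom], provenance: named}
  - {name: average_length_olfactory_to_mouth, kind: composite, op: mean,
     inputs: [olfactory_to_mouth_L, olfactory_to_mouth_R], provenance: named}
  - {name: mid_olfactory_to_chin_height,      kind: composite, op: mean,
     inputs: [olfactory_to_chin_L, olfactory_to_chin_R], provenance: named}
  - {name: neuromast_height,                  kind: composite, op: mean,
     inputs: [neuromast_height_L, neuromast_height_R], provenance: named}
  - {name: chelion_labiale_inferius_angle_difference, kind: composite, op: difference,
     inputs: [chelion_angle_L, chelion_angle_R], provenance: named}
  - {name: crista_philtri_angle_difference,   kind: composite, op: difference,
     inputs: [crista_philtri_angle_L, crista_philtri_angle_R], provenance: reconstructed}
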