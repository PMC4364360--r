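# Schema for the UCI hepatitis dataset (155 patients, 19 condition
# attributes + Die/Live outcome). The dataset itself must be obtained
# from the UCI machine learning repository by the user; it is not
# redistributed here. Cut-points for the numeric laboratory values
# follow the conventional binned domains for this dataset.
attributes:
  - {name: age, kind: numeric, role: condition, cut_points: [10, 20, 30, 40, 50, 60, 70, 80]}
  - {name: sex, kind: categorical, role: condition}
  - {name: steroid, kind: categorical, role: condition}
  - {name: antivirals, kind: categorical, role: condition}
  - {name: fatigue, kind: categorical, role: condition}
  - {name: malaise, kind: categorical, role: condition}
  - {name: anorexia, kind: categorical, role: condition}
  - {name: liver_big, kind: categorical, role: condition}
  - {name: liver_firm, kind: categorical, role: condition}
  - {name: spleen_palpable, kind: categorical, role: condition}
  - {name: spiders, kind: categorical, role: condition}
  - {name: ascites, kind: categorical, role: condition}
  - {name: varices, kind: categorical, role: condition}
  - {name: bilirubin, kind: numeric, role: condition, cut_points: [0.39, 0.80, 1.20, 2.00, 3.00, 4.00]}
  - {name: alk_phosphate, kind: numeric, role: condition, cut_points: [33, 80, 120, 160, 200, 250]}
  - {name: sgot, kind: numeric, role: condition, cut_points: [13, 100, 200, 300, 400, 500]}
  - {name: albumin, kind: numeric, role: condition, cut_points: [2.1, 3.0, 3.8, 4.5, 5.0, 6.0]}
  - {name: protime, kind: numeric, role: condition, cut_points: [10, 20, 30, 40, 50, 60, 70, 80, 90]}
  - {name: histology, kind: categorical, role: condition}
  - {name: class, kind: categorical, role: decision}
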