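# Schema for the UCI Wisconsin breast cancer (original) dataset after
# dropping the sample code number: nine integer-coded cytology features
# (1-10) and a benign(2)/malignant(4) class. Obtain the data from the
# UCI machine learning repository; it is not redistributed here.
attributes:
  - {name: clump_thickness, kind: categorical, role: condition}
  - {name: uniformity_cell_size, kind: categorical, role: condition}
  - {name: uniformity_cell_shape, kind: categorical, role: condition}
  - {name: marginal_adhesion, kind: categorical, role: condition}
  - {name: single_epithelial_cell_size, kind: categorical, role: condition}
  - {name: bare_nuclei, kind: categorical, role: condition}
  - {name: bland_chromatin, kind: categorical, role: condition}
  - {name: normal_nucleoli, kind: categorical, role: condition}
  - {name: mitoses, kind: categorical, role: condition}
  - {name: class, kind: categorical, role: decision}
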