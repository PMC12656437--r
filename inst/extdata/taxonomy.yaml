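# Canonical material taxonomy for pork-belly inspection.
# Background classes come first so loss-weight configuration can address
# them by a contiguous index range. Indices are 0-based and stable.
classes:
  - {index: 0,  name: meat,          role: background,  color: "#7a1f1f"}
  - {index: 1,  name: fat,           role: background,  color: "#f2e3c9"}
  - {index: 2,  name: conveyor_belt, role: background,  color: "#3c4048"}
  - {index: 3,  name: pa_pp,         role: contaminant, color: "#1f77b4"}
  - {index: 4,  name: pu,            role: contaminant, color: "#ff7f0e"}
  - {index: 5,  name: metal,         role: contaminant, color: "#9467bd"}
  - {index: 6,  name: pehd,          role: contaminant, color: "#2ca02c"}
  - {index: 7,  name: teflon,        role: contaminant, color: "#e377c2"}
  - {index: 8,  name: nitrile,       role: contaminant, color: "#17becf"}
  - {index: 9,  name: wood,          role: contaminant, color: "#8c564b"}
  - {index: 10, name: paper,         role: contaminant, color: "#bcbd22"}
  - {index: 11, name: cardboard,     role: contaminant, color: "#d6a26e"}
  - {index: 12, name: white_belt,    role: contaminant, color: "#c7c7c7"}
unannotated: 255
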