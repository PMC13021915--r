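# Default gating hierarchy for the 38-marker jaw-mucosa panel.
# Level 1: five basic types, priority immune > endothelial > epithelial >
#   fibroblast > functional; "any marker of a set" gates are written as one
#   rule per marker sharing a label. Cells matching nothing are unclassified.
# Level 2: immune subtypes, most specific compound gates ranked first.
rules:
  - {level: 1, label: immune,      priority: 1,  require_positive: [CD20],       require_negative: []}
  - {level: 1, label: immune,      priority: 2,  require_positive: [CD4],        require_negative: []}
  - {level: 1, label: immune,      priority: 3,  require_positive: [CD8],        require_negative: []}
  - {level: 1, label: immune,      priority: 4,  require_positive: [CD68],       require_negative: []}
  - {level: 1, label: immune,      priority: 5,  require_positive: [CD163],      require_negative: []}
  - {level: 1, label: immune,      priority: 6,  require_positive: [FoxP3],      require_negative: []}
  - {level: 1, label: immune,      priority: 7,  require_positive: [CD56],       require_negative: []}
  - {level: 1, label: immune,      priority: 8,  require_positive: [CD11c],      require_negative: []}
  - {level: 1, label: endothelial, priority: 9,  require_positive: [CD31],       require_negative: []}
  - {level: 1, label: endothelial, priority: 10, require_positive: [Podoplanin], require_negative: []}
  - {level: 1, label: endothelial, priority: 11, require_positive: [CD140b],     require_negative: []}
  - {level: 1, label: endothelial, priority: 12, require_positive: [CD146],      require_negative: []}
  - {level: 1, label: epithelial,  priority: 13, require_positive: [Ecad],       require_negative: []}
  - {level: 1, label: epithelial,  priority: 14, require_positive: [EGFR],       require_negative: []}
  - {level: 1, label: fibroblast,  priority: 15, require_positive: [Collagen1],  require_negative: []}
  - {level: 1, label: fibroblast,  priority: 16, require_positive: [CD90],       require_negative: []}
  - {level: 1, label: fibroblast,  priority: 17, require_positive: [aSMA],       require_negative: []}
  - {level: 1, label: fibroblast,  priority: 18, require_positive: [Vimentin],   require_negative: []}
  - {level: 1, label: fibroblast,  priority: 19, require_positive: [FSP1],       require_negative: []}
  - {level: 1, label: functional,  priority: 20, require_positive: [Ki67],       require_negative: []}
  - {level: 1, label: functional,  priority: 21, require_positive: [pERK],       require_negative: []}
  - {level: 1, label: functional,  priority: 22, require_positive: [BNIP3],      require_negative: []}
  - {level: 1, label: functional,  priority: 23, require_positive: [Caveolin],   require_negative: []}
  - {level: 1, label: functional,  priority: 24, require_positive: [pNFkB],      require_negative: []}
  - {level: 1, label: functional,  priority: 25, require_positive: [IntegrinB1], require_negative: []}
  - {level: 1, label: functional,  priority: 26, require_positive: [pSTAT3],     require_negative: []}
  - {level: 2, label: Treg,        priority: 1,  parent: immune, require_positive: [CD4, FoxP3],  require_negative: []}
  - {level: 2, label: exhausted T, priority: 2,  parent: immune, require_positive: [PD1, CD4],    require_negative: []}
  - {level: 2, label: exhausted T, priority: 3,  parent: immune, require_positive: [PD1, CD8],    require_negative: []}
  - {level: 2, label: BnT,         priority: 4,  parent: immune, require_positive: [CD20, CD4],   require_negative: []}
  - {level: 2, label: BnT,         priority: 5,  parent: immune, require_positive: [CD20, CD8],   require_negative: []}
  - {level: 2, label: M2,          priority: 6,  parent: immune, require_positive: [CD68, CD163], require_negative: []}
  - {level: 2, label: B,           priority: 7,  parent: immune, require_positive: [CD20],        require_negative: []}
  - {level: 2, label: CD4 T,       priority: 8,  parent: immune, require_positive: [CD4],         require_negative: [FoxP3]}
  - {level: 2, label: CD8 T,       priority: 9,  parent: immune, require_positive: [CD8],         require_negative: []}
  - {level: 2, label: macrophage,  priority: 10, parent: immune, require_positive: [CD68],        require_negative: []}
  - {level: 2, label: NK,          priority: 11, parent: immune, require_positive: [CD56],        require_negative: []}
  - {level: 2, label: DC,          priority: 12, parent: immune, require_positive: [CD11c],       require_negative: []}
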