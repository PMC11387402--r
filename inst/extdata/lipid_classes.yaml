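# Lipid class templates: sum-composition formula rules and class internal
# standards for plasma lipidomics.
#
# Each class formula is C(n + carbon_offset) H(2n + hydrogen_offset - 2d)
# plus the fixed heteroatom counts, where n = total radyl carbons and
# d = total double bonds (for sphingolipids d includes the sphingoid
# 4,5-ene). Offsets are the unique values consistent with building each
# class from its backbone + headgroup + fatty acyl condensations.
#
# Internal standards: species spiked per extraction (amount in nmol) into
# plasma_volume_uL of plasma.
plasma_volume_uL: 20
adducts:
  positive: ["[M+H]+", "[M+NH4]+", "[M+Na]+"]
  negative: ["[M-H]-", "[M+HCOO]-"]
classes:
  LPC:
    radyl_count: 1
    carbon_offset: 8
    hydrogen_offset: 18
    fixed: {"N": 1, O: 7, P: 1}
    carbon_range: [10, 30]
    db_range: [0, 12]
    internal_standard: {species: "LPC(14:0)", amount_nmol: 0.5}
  PC:
    radyl_count: 2
    carbon_offset: 8
    hydrogen_offset: 16
    fixed: {"N": 1, O: 8, P: 1}
    carbon_range: [20, 60]
    db_range: [0, 12]
    internal_standard: {species: "PC(14:0/14:0)", amount_nmol: 2.0}
  LPE:
    radyl_count: 1
    carbon_offset: 5
    hydrogen_offset: 12
    fixed: {"N": 1, O: 7, P: 1}
    carbon_range: [10, 30]
    db_range: [0, 12]
    internal_standard: {species: "LPE(14:0)", amount_nmol: 0.1}
  PE:
    radyl_count: 2
    carbon_offset: 5
    hydrogen_offset: 10
    fixed: {"N": 1, O: 8, P: 1}
    carbon_range: [20, 60]
    db_range: [0, 12]
    internal_standard: {species: "PE(14:0/14:0)", amount_nmol: 0.5}
  PI:
    radyl_count: 2
    carbon_offset: 9
    hydrogen_offset: 15
    fixed: {O: 13, P: 1}
    carbon_range: [20, 60]
    db_range: [0, 12]
    internal_standard: {species: "PI(8:0/8:0)", amount_nmol: 0.5}
  PS:
    radyl_count: 2
    carbon_offset: 6
    hydrogen_offset: 10
    fixed: {"N": 1, O: 10, P: 1}
    carbon_range: [20, 60]
    db_range: [0, 12]
    internal_standard: {species: "PS(14:0/14:0)", amount_nmol: 5.0}
  PG:
    radyl_count: 2
    carbon_offset: 6
    hydrogen_offset: 11
    fixed: {O: 10, P: 1}
    carbon_range: [20, 60]
    db_range: [0, 12]
    internal_standard: {species: "PG(14:0/14:0)", amount_nmol: 0.1}
  LPG:
    radyl_count: 1
    carbon_offset: 6
    hydrogen_offset: 13
    fixed: {O: 9, P: 1}
    carbon_range: [10, 30]
    db_range: [0, 12]
    internal_standard: {species: "LPG(14:0)", amount_nmol: 0.02}
  PA:
    radyl_count: 2
    carbon_offset: 3
    hydrogen_offset: 5
    fixed: {O: 8, P: 1}
    carbon_range: [20, 60]
    db_range: [0, 12]
    internal_standard: {species: "PA(14:0/14:0)", amount_nmol: 0.5}
  LPA:
    radyl_count: 1
    carbon_offset: 3
    hydrogen_offset: 7
    fixed: {O: 7, P: 1}
    carbon_range: [10, 30]
    db_range: [0, 12]
    internal_standard: {species: "LPA(14:0)", amount_nmol: 0.1}
  CL:
    radyl_count: 4
    carbon_offset: 9
    hydrogen_offset: 14
    fixed: {O: 17, P: 2}
    carbon_range: [40, 88]
    db_range: [0, 12]
    internal_standard: {species: "CL(14:0/14:0/14:0/14:0)", amount_nmol: 0.1}
  SM:
    radyl_count: 2
    carbon_offset: 5
    hydrogen_offset: 13
    fixed: {"N": 2, O: 6, P: 1}
    carbon_range: [20, 60]
    db_range: [0, 12]
    internal_standard: {species: "SM(d18:1/12:0)", amount_nmol: 2.125}
  Cer:
    radyl_count: 2
    carbon_offset: 0
    hydrogen_offset: 1
    fixed: {"N": 1, O: 3}
    carbon_range: [20, 60]
    db_range: [0, 12]
    internal_standard: {species: "Cer(d18:1/12:0)", amount_nmol: 0.125}
  DG:
    radyl_count: 2
    carbon_offset: 3
    hydrogen_offset: 4
    fixed: {O: 5}
    carbon_range: [20, 60]
    db_range: [0, 12]
    internal_standard: {species: "DG(14:0/14:0)", amount_nmol: 0.5}
  TG:
    radyl_count: 3
    carbon_offset: 3
    hydrogen_offset: 2
    fixed: {O: 6}
    carbon_range: [30, 80]
    db_range: [0, 12]
    internal_standard: {species: "TG(14:0/14:0/14:0)", amount_nmol: 0.5}
  CE:
    radyl_count: 1
    carbon_offset: 27
    hydrogen_offset: 44
    fixed: {O: 2}
    carbon_range: [10, 30]
    db_range: [0, 12]
    internal_standard: {species: "D7-CE(16:0)", amount_nmol: 2.5}
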