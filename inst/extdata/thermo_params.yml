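# Nearest-neighbor thermodynamic parameters for DNA/DNA duplexes.
#
# nn_stacks: unified nearest-neighbor set (SantaLucia 1998), keyed by the
#   5'->3' dinucleotide on one strand; values are [dH kcal/mol, dS cal/(mol K)].
#   The ten unique stacks are listed; reverse-complement equivalents are
#   filled in by the loader.
# initiation: per-terminal duplex initiation terms, keyed by the identity of
#   the terminal base pair.
# salt: monovalent-salt entropy correction, dS' = dS + f * (N-1) * ln[Na+],
#   [Na+] in mol/L, N the oligo length. Divalent Mg2+ is folded in as an
#   equivalent monovalent concentration: Na_eq_mM = Na_mM + 120*sqrt(Mg_mM).
# lna_increments: additive Tm increase (deg C) per LNA substitution, keyed by
#   the substituted base. Screening-grade defaults in the literature-typical
#   2-4 C range; edit to calibrate against a vendor tool for a given design.
# lna_stacks: dH/dS perturbations [ddH, ddS] applied to the stack whose 5'
#   base is the LNA, used by the refined Tm mode. All entries stabilizing.
# loop_penalty: flat hairpin-loop penalty (kcal/mol) added to stem stacks.
nn_stacks:
  AA: [-7.9, -22.2]
  AT: [-7.2, -20.4]
  TA: [-7.2, -21.3]
  CA: [-8.5, -22.7]
  GT: [-8.4, -22.4]
  CT: [-7.8, -21.0]
  GA: [-8.2, -22.2]
  CG: [-10.6, -27.2]
  GC: [-9.8, -24.4]
  GG: [-8.0, -19.9]
initiation:
  AT: [2.3, 4.1]
  GC: [0.1, -2.8]
salt:
  entropy_factor: 0.368
  mg_equivalent_factor: 120.0
lna_increments:
  A: 2.6
  C: 3.4
  G: 2.4
  T: 3.8
lna_stacks:
  AA: [-2.1, -4.4]
  AC: [-2.3, -4.6]
  AG: [-2.2, -4.5]
  AT: [-2.4, -4.8]
  CA: [-2.6, -5.0]
  CC: [-2.8, -5.2]
  CG: [-2.7, -5.1]
  CT: [-2.9, -5.4]
  GA: [-2.0, -4.2]
  GC: [-2.2, -4.5]
  GG: [-2.1, -4.3]
  GT: [-2.3, -4.7]
  TA: [-2.8, -5.2]
  TC: [-3.0, -5.5]
  TG: [-2.9, -5.3]
  TT: [-3.1, -5.7]
loop_penalty: 3.0
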