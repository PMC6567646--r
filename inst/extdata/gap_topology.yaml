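# Default gap-gene network topology.
#
# Topology is data, not code: edges are (regulator, target, mode, class) and
# each named model variant overlays an affinity map (class -> affinity label)
# on this base network.  Edit this file (or pass an alternative via
# `build_model(topology = ...)`) to correct or extend the network without
# touching code.
#
# Classes follow the regulator^role naming: e.g. Bcd_A is "Bicoid as
# activator", Kr_R is "Kruppel as repressor", Hb_D is the dual (activating at
# low, repressing at high concentration) action of Hunchback on Kruppel.
# The Bcd_R and Hb_A classes have no default targets; add edges here to use
# them (they resolve to the global affinity K in every variant).

genes:
  dynamic: [Hb, Kr, Kni, Gt]
  static: [Bcd, Cad, Tll, Hb_maternal]

max_concentration: 50

edges:
  - {regulator: Bcd, target: Hb,  mode: activator, class: Bcd_A}
  - {regulator: Bcd, target: Kni, mode: activator, class: Bcd_A}
  - {regulator: Bcd, target: Gt,  mode: activator, class: Bcd_A}
  - {regulator: Cad, target: Kni, mode: activator, class: Cad_A}
  - {regulator: Cad, target: Gt,  mode: activator, class: Cad_A}
  - {regulator: Hb,  target: Kr,  mode: dual,      class: Hb_D}
  - {regulator: Hb,  target: Kni, mode: repressor, class: Hb_R}
  - {regulator: Kr,  target: Gt,  mode: repressor, class: Kr_R}
  - {regulator: Gt,  target: Kr,  mode: repressor, class: Gt_R}
  - {regulator: Kni, target: Hb,  mode: repressor, class: Kni_R}
  - {regulator: Tll, target: Kr,  mode: repressor, class: Tll_R}
  - {regulator: Tll, target: Kni, mode: repressor, class: Tll_R}
  - {regulator: Tll, target: Gt,  mode: repressor, class: Tll_R}

# Extra edges switched on by specific model variants (D7, D8 add Bcd -> Kr).
extra_edges:
  D7:
    - {regulator: Bcd, target: Kr, mode: activator, class: Bcd_A}
  D8:
    - {regulator: Bcd, target: Kr, mode: activator, class: Bcd_A}

# Every class resolves to the global affinity K unless overridden.
affinity_base:
  Hb_R: K1

affinity_overrides:
  A6:  {Kr_R: K1}
  B7:  {Kr_R: K2}
  B7r: {Kr_R: K1, Bcd_A: K3}
  C8:  {Kr_R: K2, Bcd_A: K3}
  D7:  {Kr_R: K2}
  D8:  {Kr_R: K2, Bcd_A: K3}
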