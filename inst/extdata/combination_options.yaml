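# Eligible scoring functions per varied interaction group, one row per
# combination strategy. Human-editable: counts downstream are data-driven.
# The six varied groups are the frequently used interaction types; all other
# groups are retained in default during assembly.
formula:
  vdw: [GalaxyDock BP2, Goldscore, Smina]
  hbond: [GalaxyDock BP2, Goldscore, Smina]
  elec: [GalaxyDock BP2, NNScore]
  hydrophobic: [Chemscore, Affiscore, X-score, Glide XP]
  entropy: [SMoG2016, Glide XP]
  clash: [Chemscore, ChemPLP]
tree_sum:
  vdw: [Glide SP]
  hbond: [ChemPLP]
  elec: [Autodock, Glide XP]
  hydrophobic: [Glide XP, Affiscore, Chemscore]
  entropy: [SMoG2016, Chemscore]
  clash: [ChemPLP, ASP]
tree_mean:
  vdw: [Smina]
  hbond: [Smina]
  elec: [NNScore]
  hydrophobic: [Glide XP, Smina]
  entropy: [SMoG2016, Glide XP, Chemscore]
  clash: [ChemPLP, ASP]
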