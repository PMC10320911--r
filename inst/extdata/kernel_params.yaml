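# Pair-kernel parameters for the native descriptor blocks. All distances in
# Angstrom; surface distance d = r - R_i - R_j. Defaults follow Vina/Smina
# conventions (steric triple with the published default weights) and
# BINANA-style contact shells; deviations from these values are auditable here.
cutoff: 8.0
vina:
  gauss1: {offset: 0.0, width: 0.5, weight: -0.035579}
  gauss2: {offset: 3.0, width: 2.0, weight: -0.005156}
  repulsion: {weight: 0.840245}
hbond_pl: {full: -0.7, zero: 0.0}
hydrophobic_pl: {full: 0.5, zero: 1.5}
elec: {constant: 332.0, dielectric: distance_dependent, epsilon: 4.0}
desolvation: {sigma: 3.6}
hbond_geom: {ha_max: 2.5, da_max: 3.5, angle_min: 120.0}
nnscore: {close_max: 2.5, semi_max: 4.0, hydrophobic_max: 4.0, elec_max: 4.0}
metal: {full: 2.2, zero: 4.0}
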