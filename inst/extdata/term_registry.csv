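scoring_function,term,group
Autodock,vdw,vdw
Autodock,hbond,hbond
Autodock,elec,elec
Autodock,tor,entropy
Autodock,sol,sol
Affiscore,polar,hbond
Affiscore,sol,sol
Affiscore,hydrophobic,hydrophobic
Affiscore,entropy,entropy
ASP,internal,internal
ASP,clash,clash
ASP,map,knowledge
Chemscore,hbond,hbond
Chemscore,entropy,entropy
Chemscore,internal,internal
Chemscore,clash,clash
Chemscore,hydrophobic,hydrophobic
Chemscore,metal,metal
DSX,pair,knowledge
DSX,internal,internal
DSX,sol,sol
GalaxyDock BP2,vdw,vdw
GalaxyDock BP2,hbond,hbond
GalaxyDock BP2,elec,elec
GalaxyDock BP2,sol,sol
GalaxyDock BP2,internal,internal
GalaxyDock BP2,hydrophobic,hydrophobic
GalaxyDock BP2,drugscore,knowledge
Goldscore,vdw,vdw
Goldscore,hbond,hbond
Goldscore,internal,internal
NNScore,vdw,vdw
NNScore,hbond,hbond
NNScore,hydrophobic,hydrophobic
NNScore,nn_pair,nn_pair
NNScore,nn_elec,elec
ChemPLP,hbond,hbond
ChemPLP,metal,metal
ChemPLP,clash,clash
ChemPLP,plp,knowledge
ChemPLP,internal,internal
Smina,vdw,vdw
Smina,hbond,hbond
Smina,elec,elec
Smina,hydrophobic,hydrophobic
Smina,non_hydrophobic,non_hydrophobic
Smina,sol,sol
SMoG2016,vdw,vdw
SMoG2016,entropy,entropy
SMoG2016,KBP2016,knowledge
Glide SP,vdw,vdw
Glide SP,hbond,hbond
Glide SP,elec,elec
Glide SP,hydrophobic,hydrophobic
Glide SP,metal,metal
Glide SP,entropy,entropy
Glide XP,vdw,vdw
Glide XP,hbond,hbond
Glide XP,elec,elec
Glide XP,hydrophobic,hydrophobic
Glide XP,metal,metal
Glide XP,entropy,entropy
Glide XP,pi_cation,elec
Vina,vdw,vdw
Vina,entropy,entropy
Vina,hbond,hbond
Vina,hydrophobic,hydrophobic
X-score,vdw,vdw
X-score,entropy,entropy
X-score,hbond,hbond
X-score,hydrophobic,hydrophobic
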