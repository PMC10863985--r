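# Published sigmoid / scaling constants used by the scoring and validation
# functions. Values are transcribed from the primary publications of each
# score so that they are auditable in one place rather than hard-coded.
pdockq:
  # Bryant P, Pozzati G, Elofsson A (2022) Nat Commun 13:1265.
  # pDockQ = L / (1 + exp(-k * (x - x0))) + b,
  # x = <interface pLDDT> * ln(n interface contacts),
  # contacts: C-beta pairs (C-alpha for Gly) within cb_cutoff Angstrom.
  L: 0.724
  x0: 152.611
  k: 0.052
  b: 0.018
  cb_cutoff: 8.0
pdockq2:
  # Zhu W, Shenoy A, Kundrotas P, Elofsson A (2023) Bioinformatics 39:btad424.
  # Per chain i: X_i = <pLDDT over interface residues of i> *
  #                    <1 / (1 + (PAE_ij / d0)^2) over interchain contact pairs>,
  # pDockQ2_i = L / (1 + exp(-k * (X_i - x0))) + b; complex score = mean over chains.
  L: 1.31
  x0: 84.733
  k: 0.075
  b: 0.005
  d0: 10.0
  cb_cutoff: 8.0
  pae_max: 31.75
dockq:
  # Basu S, Wallner B (2016) PLoS ONE 11:e0161879.
  # DockQ = (Fnat + 1/(1+(iRMS/d1)^2) + 1/(1+(LRMS/d2)^2)) / 3
  d1: 1.5
  d2: 8.5
  fnat_cutoff: 5.0
  interface_cutoff: 10.0
tm_score:
  # Zhang Y, Skolnick J (2004) Proteins 57:702-710.
  # d0 = 1.24 * (L - 15)^(1/3) - 1.8, floored at d0_min.
  d0_coef: 1.24
  d0_sub: 15
  d0_shift: 1.8
  d0_min: 0.5
vdw_radii:
  # Bondi A (1964) J Phys Chem 68:441-451 (element-based set).
  "H": 1.20
  "C": 1.70
  "N": 1.55
  "O": 1.52
  "S": 1.80
  "P": 1.80
  "SE": 1.90
  default: 1.80
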