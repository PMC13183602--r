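cell_type: mTAL
sex: female
water_permeable: no
cytosol_H: 6.3095734448019293e-05
lumen:
  concentrations:
    Na: 140.0
    K: 6.0
    Cl: 146.0
  H_concentration: 0.0001
  impermeant_conc: 0.0001
  impermeant_valence: -1
  neutral_osm: 0.0
interstitium:
  concentrations:
    Na: 140.0
    K: 5.0
    Cl: 145.0
  H_concentration: 3.98107170553496878e-05
  impermeant_conc: 3.98107170553496878e-05
  impermeant_valence: -1
  neutral_osm: 0.0
membranes:
  apical:
    permeabilities:
      Na: 1.00000000000000002e-08
      K: 3.30000000000000017e-06
      Cl: 1.00000000000000002e-08
    Pf: 0.0
  basolateral:
    permeabilities:
      Na: 2.00000000000000004e-08
      K: 4.50000000000000011e-06
      Cl: 3.99999999999999982e-06
    Pf: 0.0
  paracellular:
    permeabilities:
      Na: 3.99999999999999982e-07
      K: 3.99999999999999982e-07
      Cl: 1.99999999999999991e-07
    Pf: 0.0
activities:
  x_NHE3: 0.0
  x_SGLT2: 0.0
  x_NBCe1: 0.0
  x_NKCC2: 2.06999999999999968e-08
  pump_Jmax: 0.00108
  pump_K_Na: 15.0
  pump_K_K: 5.0
geometry:
  volume: 0.0005
  impermeant_amount: 0.0575
  impermeant_valence: -1
sex_factors:
  NKCC2: 1.14999999999999991
  pump: 0.90000000000000002
  PK_api: 1.10000000000000009
  PK_bas: 0.90000000000000002
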