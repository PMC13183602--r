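cell_type: PCT
sex: female
water_permeable: yes
cytosol_H: 6.3095734448019293e-05
lumen:
  concentrations:
    Na: 140.0
    K: 5.0
    Cl: 113.0
    HCO3: 25.0
    glucose: 5.0
  H_concentration: 0.00015848931924611
  impermeant_conc: 7.00015848931924634
  impermeant_valence: -1
  neutral_osm: 0.0
interstitium:
  concentrations:
    Na: 140.0
    K: 5.0
    Cl: 113.0
    HCO3: 25.0
    glucose: 5.0
  H_concentration: 3.98107170553496878e-05
  impermeant_conc: 7.00003981071705539
  impermeant_valence: -1
  neutral_osm: 0.00023735720435525
membranes:
  apical:
    permeabilities:
      Na: 2.00000000000000004e-08
      K: 1.99999999999999991e-06
      Cl: 1.00000000000000002e-08
      HCO3: 1.00000000000000002e-08
      glucose: 1.00000000000000002e-08
    Pf: 0.05
  basolateral:
    permeabilities:
      Na: 2.00000000000000004e-08
      K: 3.99999999999999982e-06
      Cl: 9.99999999999999955e-07
      HCO3: 3.00000000000000008e-06
      glucose: 1.00000000000000008e-05
    Pf: 0.05
  paracellular:
    permeabilities:
      Na: 9.99999999999999955e-07
      K: 9.99999999999999955e-07
      Cl: 9.99999999999999955e-07
      HCO3: 0.0
      glucose: 0.0
    Pf: 0.0
activities:
  x_NHE3: 0.00021
  x_SGLT2: 1.49999999999999987e-08
  x_NBCe1: 8.50000000000000001e-09
  x_NKCC2: 0.0
  pump_Jmax: 0.0009775
  pump_K_Na: 15.0
  pump_K_K: 5.0
geometry:
  volume: 0.001
  impermeant_amount: 0.10299999999999999
  impermeant_valence: -1
sex_factors:
  NHE3: 0.69999999999999996
  pump: 0.84999999999999998
  NBCe1: 0.84999999999999998
  PK_bas: 1.0
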