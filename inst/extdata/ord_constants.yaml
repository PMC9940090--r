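# Model constants of the cipaddi ventricular myocyte simulator.
# Values and sources:
#  - base_conductances: maximal conductances/permeabilities of the
#    endocardial cell, O'Hara & Rudy 2011 (undiseased human ventricular
#    myocyte model), supplementary equations; units as in that model.
#  - cipa_scaling: conductance rescaling factors from Dutta et al. 2017
#    (CiPA in silico model optimization, FDA CiPA model v1.0).
#  - stimulus: FDA CiPA protocol default pacing pulse.
#  - qnet_thresholds: TdP risk thresholds (uC/uF) from the ordinal
#    regression calibration of Li et al. over the CiPA training drugs.
#  - initial_state: published O'Hara 2011 endocardial initial conditions;
#    hERG Markov gating states (Li et al. 2017, hIC1..hIO) start closed.
#  The package code is the canonical source; a unit test asserts this
#  file stays in agreement with it.
base_conductances:
  GNa: 75
  GNaL: 0.0075
  Gto: 0.02
  PCa: 0.0001
  GKr: 0.046
  GKs: 0.0034
  GK1: 0.1908
  Gncx: 0.0008
  Pnak: 30
  GKb: 0.003
  PNab: 3.75e-10
  PCab: 2.5e-08
  GpCa: 0.0005
cipa_scaling:
  NaL: 2.661
  CaL: 1.007
  Kr: 1.013
  Ks: 1.87
  K1: 1.698
stimulus:
  amplitude_uA_per_uF: -80
  duration_ms: 0.5
  cycle_length_ms: 2000
qnet_thresholds:
  threshold1: 0.0652
  threshold2: 0.0516
initial_state:
  v: -87.5
  nai: 7.268
  nass: 7.268
  ki: 144.65
  kss: 144.65
  cai: 8.6e-05
  cass: 8.49e-05
  cansr: 1.61
  cajsr: 1.56
  m: 0.0074621
  hf: 0.692591
  hs: 0.692574
  j: 0.692477
  hsp: 0.448501
  jp: 0.692413
  mL: 0.000194015
  hL: 0.496116
  hLp: 0.265885
  a: 0.00101185
  iF: 0.999542
  iS: 0.589579
  ap: 0.000515567
  iFp: 0.999542
  iSp: 0.641861
  d: 2.43015e-09
  ff: 1
  fs: 0.910671
  fcaf: 1
  fcas: 0.99982
  jca: 0.999977
  nca: 0.00267171
  ffp: 1
  fcafp: 1
  xrf: 8.26608e-06
  xrs: 0.453268
  xs1: 0.270492
  xs2: 0.0001963
  xk1: 0.996801
  Jrelnp: 2.53943e-05
  Jrelp: 3.17262e-07
  CaMKt: 0.0124065
  hIC1: 0
  hIC2: 0
  hC1: 0
  hC2: 1
  hO: 0
  hIO: 0
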