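# Default structural and elastic parameters of the four double-stranded DNA
# forms used by the multistate transfer-matrix model.
#
#   Lp            bending persistence length, nm
#   Ltw           twisting persistence length, nm
#   contour_ratio base-pair rise relative to B-DNA (rise_B = 0.33 nm)
#   h             helical repeat, bp per turn (always positive)
#   handedness    +1 right-handed helix, -1 left-handed helix
#   mu            base-pairing free energy per bp relative to B-DNA, kBT
#   lam           Fuller-correction weight lambda (dimensionless)
#
# B is the reference state: mu = 0, relaxed linking density offset 0.
rise_B_nm: 0.33
states:
  B: {Lp: 50.0, Ltw: 95.0, contour_ratio: 1.0,  h: 10.4, handedness: 1,  mu: 0.0,  lam: 4.3}
  L: {Lp: 7.0,  Ltw: 15.0, contour_ratio: 1.35, h: 16.0, handedness: -1, mu: 5.0,  lam: 4.3}
  P: {Lp: 15.0, Ltw: 25.0, contour_ratio: 1.7,  h: 3.0,  handedness: 1,  mu: 17.8, lam: -0.5}
  S: {Lp: 15.0, Ltw: 20.0, contour_ratio: 1.7,  h: 35.0, handedness: 1,  mu: 5.1,  lam: 4.3}
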