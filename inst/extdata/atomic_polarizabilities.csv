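# Per-element isotropic excess polarizabilities (A^3) in the package volume
# convention (alpha = 3V (np^2-nm^2)/(np^2+2nm^2) for a sphere; scattering
# cross-section k^4 alpha^2 / 6 pi).
# Relative magnitudes: in-vacuo static atomic polarizabilities (CRC compilation;
# ionic values for metals bound in proteins). Absolute scale: calibrated so the
# averagine heavy-atom composition (C4.938 N1.358 O1.477 S0.042 per residue,
# 103.30 Da heavy-atom mass) yields 724 A^3 per kDa of heavy-atom mass,
# the mass-polarizability slope of folded proteins. Swap this file to use a
# different parameterization.
element,alpha_a3
H,4.341
C,11.455
N,7.159
O,5.220
S,18.874
P,23.626
SE,24.537
F,3.625
CL,14.188
BR,19.851
I,34.820
FE,3.254
ZN,1.887
MG,3.189
CA,3.059
NA,1.172
K,5.467
MN,3.254
CU,1.953
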