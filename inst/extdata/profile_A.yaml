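# Calibrated reference parameter profile "A" of the promoter model.
# Energies in kT, rates per day; see ?epi_params for field meanings.
profile: A
F_TF: 1.0
eps_BS: 5.0
D_novo_0: 0.1
phi: 1.0
tau: 1.0
eps0: 15.0
d0_4: -0.5
eps_c4: 10.0
eps_c27: 20.0
eps_T: 1.0
eps_x: 1.0
eps_F: 12.0
k_m: 3.0
k_d: 1.0
k_tr: 0.088
lambda: 4.0
a_T: 90.0
b_T: 36.0
p0: 0.0
h_maint: 4.0
K_maint: 0.3
m4_max: 0.75
m27_max: 0.75
N_nuc: 20
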