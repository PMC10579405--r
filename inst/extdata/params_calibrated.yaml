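mu_bt_G: 0.56
mu_ri_G: 0.5
mu_bt_M: 0.033
mu_ri_M: 0.0
mu_ri_A: 0.02
K_G: 0.4
K_M: 0.5
K_A: 2.0
KI_M_ri: 0.4
KI_G_bt: 0.25
Y_bt_G: 80000.0
Y_ri_G: 52000.0
Y_bt_M: 60000.0
Y_ri_A: 50000.0
p_A_bt: 1.5
p_X_bt: 1.0
p_A_ri: 0.93
p_Bu_ri: 0.4
p_Bu_A: 0.5
r_M: 2.5e-06
f_att_bt: 0.33
f_att_ri: 0.25
k_switch_bt: 0.5
k_switch_ri: 0.35
theta_G: 0.5
theta_M: 0.4
switch_eps: 0.08
d_bt: 0.032
d_ri: 0.032
pH0: 6.7
c_pH: 0.045
pH_floor: 4.0
pH_half_bt: 5.5
pH_half_ri: 4.8
n_pH: 16.0
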