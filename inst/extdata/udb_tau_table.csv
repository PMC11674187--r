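# Published per-experiment time constants from use-dependent block analysis of
# cenobamate on hNav1.5 (four cells): drug-free inactivation (tau_i) and
# recovery (tau_r) time constants, apparent decay constant with drug
# (tau_i_ob), and the estimated inactivated-state block/unblock constant
# (tau_ib_est). All values in ms.
experiment,tau_i,tau_r,tau_i_ob,tau_ib_est
23o10,2.36,3.31,2.23,4.08
a3o10,2.62,3.76,3.04,3.83
b3o10,2.93,5.13,2.94,4.94
c3o10,1.95,3.04,1.73,3.25
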