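# Published apparent inactivation time constants (ms) of peak I_Na decay,
# fitted in the same cell initially and at 3 min after application of
# cenobamate 200 uM (condition "cenobamate") or of the same amount of vehicle
# only (condition "vehicle"). Rows flagged excluded = TRUE were left out of
# further analysis due to recording artifacts (adjacent gap-junction-coupled
# cell) and are honored as exclusions here.
experiment,condition,tau_initial,tau_after,excluded
23314,cenobamate,1.19,0.67,FALSE
23317,cenobamate,1.63,0.83,FALSE
23321,cenobamate,3.49,1.21,TRUE
a3321,cenobamate,0.87,0.56,FALSE
23324,cenobamate,0.67,0.58,FALSE
a3324,cenobamate,0.98,0.56,FALSE
23311,vehicle,1.96,1.86,FALSE
23325,vehicle,1.89,1.88,FALSE
23517,vehicle,4.00,4.06,FALSE
23519,vehicle,2.09,2.04,FALSE
a3519,vehicle,0.78,0.79,FALSE
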