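# Published mean fractional inhibition values (cenobamate at 200 uM vs
# time-matched vehicle controls) used for single-point IC50 estimation.
# control_corrected says whether the published IC50 subtracted the control
# rundown before inverting the Hill relation.
channel,concentration_um,inhibition_drug,inhibition_control,control_corrected
INa_peak,200,0.6953,0.0078,FALSE
ICaL,200,0.3926,0.0310,FALSE
IKs,200,0.3668,0.2366,TRUE
IKr,200,0.1097,0.0410,TRUE
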