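subtype	ecm_low	ecm_high
primitive	12	9
classical	61	33
secretory	7	41
basal	14	46
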