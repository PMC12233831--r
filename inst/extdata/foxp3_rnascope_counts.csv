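donor,n_colocalized,n_upa_only
HD45,850,1713
HD46,737,1347
HD49,122,647
HD50,391,1151
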