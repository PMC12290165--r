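subject_id,scan_available
P001,1
P002,1
P003,1
P004,1
P005,1
P006,0
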