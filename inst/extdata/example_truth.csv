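subject_id,truth
S001,AD
S002,CN
S003,AD
S004,CN
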