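{"schema":"thyronod_targets_v1","benign_fraction":0.878961887068626,"weights":{"incidence":1,"size":1,"benign_fraction":0.5,"benign_size":0.1}}
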