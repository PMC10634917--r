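units: nm
pixel_size_nm: 160.0
n_frames: 3000.0
target_id: PSD95
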