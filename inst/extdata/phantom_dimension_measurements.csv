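item,measurement_1_mm,measurement_2_mm,ground_truth_mm
rod_inner_diameter,58.5,58.9,58.5
body_inner_length,149.3,149.8,150.1
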