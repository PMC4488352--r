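{"mu_r":2.30459956492674,"sigma_r":0.032069776104705,"mu_p":1.50037359999792,"sigma_p":0.0341240965284155,"mu_t":1.74523335146935,"sigma_t":0.0172437526226378,"sigma_delta":0.0132181147901169,"t_unit":"radians"}
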