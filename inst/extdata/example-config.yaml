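# Minimal simulation configuration: ventricular labeling at E32, analysed
# at E34.5 and E36 (embryonic days; P0 = E42).
seed: 7
t0: 32
t_end: 36
founders: {count: 15, type: ARGC, layer: VZ}
injection: {site: VENTRICLE, time: 32, n_infected: 10}
analysis_times: [34.5, 36]
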