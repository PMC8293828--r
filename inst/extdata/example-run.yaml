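# Five-site chain in the intermediate-coupling regime, adaptive propagation.
n_sites: 5
V: 50            # nearest-neighbor coupling, cm-1
lambda: 50       # reorganization energy, cm-1
gamma: 50        # bath relaxation rate, cm-1
temperature: 295 # K
gamma_mark: 500  # Markovian correction rate, cm-1
variant: adaptive
k_max: 10
delta: 1.0e-3
dt: 2            # fs
t_max: 400       # fs
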