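# Two-state exchange preset: E 0.25 / 0.80 interconverting at 1/ms each
# way, 0.5 ms mean burst duration, 100 photons/ms.
out: two_state_photons.csv
R0: 50
tau_D0: 4
seed: 1
efficiencies: [0.25, 0.80]
rates: [1.0, 1.0]
count_rate: 100
n_bursts: 1000
diffusion_time: 0.5
min_photons: 50
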