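# Cytosine in an argon matrix: system descriptor and reference model
# parameters (energies eV, times ps).
n_chromophore_atoms = 13
n_solvent_atoms = 684
photon_energy_ev = 5.25
e0_chromophore_ev = 1.46
e0_solvent_ev = 0.89
n_pathways = 2
n_channels = 1
fit_window_ps = 3
# reference model parameters for simulate/generate; heating amplitudes
# inverted from the published A_i coefficients
pathway_weights = 0.16, 0.84
pathway_times_ps = 0.0070, 0.760
heating_amplitudes_ev = 6.061, 1.789
cooling_time_ps = 24.9
solvent_times_ps = 15.49
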