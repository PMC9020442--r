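# Cytosine in water: system descriptor and reference model parameters
# (energies eV, times ps).
n_chromophore_atoms = 13
n_solvent_atoms = 900
photon_energy_ev = 5.25
e0_chromophore_ev = 1.43
e0_solvent_ev = 34.66
n_pathways = 2
n_channels = 1
fit_window_ps = 1.5
# reference model parameters for simulate/generate; heating amplitudes
# inverted from the published A_i coefficients (A_2 = 0 pins kappa_2 = 0)
pathway_weights = 0.33, 0.67
pathway_times_ps = 0.046, 0.903
heating_amplitudes_ev = 5.028, 0.0
cooling_time_ps = 1.3
solvent_times_ps = 0.15
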