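# Example experiment configuration for run_config() / `atriasim run`:
# pace the AF-4-remodelled right atrial cell for ten beats at 1 Hz.
experiment: cell_pace
region: RA
af: AF4
bcl: 1000
n_beats: 10
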