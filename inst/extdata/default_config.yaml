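# Default software-targeting configuration (hg19).
# Target intervals are a documented reconstruction of established
# syndrome critical regions; the published source lists bands only.
backbone_min_size: 3000000
min_probes: 3
min_probes_full_res: 3
segmentation_threshold: 6
adjacency_gap: 1000000
min_reference_arrays: 5
deviation_threshold: 0.3
mosaic_window: [0.25, 0.8]
min_target_overlap: 1
targets_bed: default_targets.bed
exclusions_bed: default_exclusions.bed
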