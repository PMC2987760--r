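# Synthetic bundle configuration reproducing the cardinal structure of the
# motivating comparative-transcriptomics analysis: three pooled disease
# studies (419 up, 301 down, 716-gene universe), a drug set whose human
# homologs hit 56/41/16 of those, and a KEGG-like pathway plan.
n_studies: 3
pooled_up: 419
pooled_down: 301
pooled_universe: 716
drug_in_universe: 56
drug_in_up: 41
drug_in_down: 16
drug_source_size: 150
drug_extra_targets: 30
multiplicity_probs: [0.15, 0.70, 0.15]
study_overlap_prob: 0.15
inject_symbols: [BRAF, PAK1, PRKCA]
source_species: drosophila
target_species: human
seed: 20101028
pathway_plan:
  - {name: MAPK_SIGNALING, background_hits: 9, foreground_hits: 3, decoy_size: 200}
  - {name: METABOLIC_PATHWAYS, background_hits: 36, foreground_hits: 6, decoy_size: 900}
  - {name: FOCAL_ADHESION, background_hits: 9, foreground_hits: 3, decoy_size: 180}
  - {name: ERBB_SIGNALING, background_hits: 7, foreground_hits: 3, decoy_size: 80}
  - {name: ARGININE_PROLINE_METABOLISM, background_hits: 7, foreground_hits: 3, decoy_size: 40}
  - {name: NK_CELL_CYTOTOXICITY, background_hits: 5, foreground_hits: 3, decoy_size: 120}
  - {name: VSMC_CONTRACTION, background_hits: 7, foreground_hits: 3, decoy_size: 110}
  - {name: NULL_PATHWAY_1, background_hits: 12, foreground_hits: 1, decoy_size: 100}
  - {name: NULL_PATHWAY_2, background_hits: 10, foreground_hits: 1, decoy_size: 90}
  - {name: NULL_PATHWAY_3, background_hits: 8, foreground_hits: 1, decoy_size: 60}
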