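# Demo synthetic-collection spec: three species with planted homologs of the
# synthetic demo catalog at 4:2:1 abundance, on a decoy background.
seed: 11
decoys_per_genome: 12
decoy_length_range: [80, 200]
species:
  - label: Species_high
    n_genomes: 2
    planted:
      - reference: SYN_MCO_01
        copies_per_genome: 4
        target_identity: 0.8
      - reference: SYN_CUT_01
        copies_per_genome: 1
        target_identity: 0.75
  - label: Species_mid
    n_genomes: 2
    planted:
      - reference: SYN_MCO_01
        copies_per_genome: 2
        target_identity: 0.8
  - label: Species_low
    n_genomes: 1
    planted:
      - reference: SYN_MCO_01
        copies_per_genome: 1
        target_identity: 0.8
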