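# Annotated synthetic-cohort specification for `dera synth --spec`.
n_genes: 30            # genes in the random prior network
n_edges: 50            # signed directed edges (no self-loops generated)
inhibition_fraction: 0.3
n_reference: 10        # control samples defining baseline expression
effect_size_log2: 2.0  # |log2 shift| applied to both genes of an active
                       # planted regulation (one unit above the K=2 cutoff)
noise_sd_log2: 0.3     # per-entry Gaussian noise on the log2 scale
seed: 1
groups:                # one entry per phenotype group
  - label: caseA
    n_samples: 40
  - label: caseB
    n_samples: 40
planted:               # planting recipe; group "shared" = all groups
  - group: shared
    n_instances: 5
    prevalence: 0.7    # per-sample Bernoulli activation probability
  - group: caseA
    n_instances: 3
    prevalence: 0.8
  - group: shared
    n_instances: 5
    prevalence: 0.2    # decoys: below the discovery threshold T = 0.5
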