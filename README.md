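# tmekit

Tools for dissecting tumor microenvironment (TME) interactions in
single-cell RNA-seq and multiplex immunofluorescence (MxIF) data, built
around two analyses used to study cancer-associated fibroblasts (CAFs) in
mouse colorectal tumor models:

1. **Receptor–ligand (RL) communication scoring.** Given a gene×cell count
   matrix, a cell annotation (cell type, biological-replicate sample,
   condition group), and a prior-knowledge table of directed ligand→receptor
   interactions, the pipeline quantifies candidate signaling from a sender
   cell type (e.g. CAFs) to a receiver cell type (e.g. tumor or squamous
   cells) and flags interactions that replicate across every sample of a
   condition group.
2. **MxIF mask quantification.** Given a multichannel immunofluorescence
   image, marker channels are thresholded into binary masks, fibroblast
   subtypes are defined by marker co-positivity (CAF1 = SMA⁺VIM⁺,
   CAF2 = PDGFRα⁺TNC⁺), and subtype abundance is measured as positive area
   inside the tumor region normalized to the tumor-marker (β-catenin) mask
   area, with a pooled-variance Student's t-test between groups.

A synthetic-data module generates negative-binomial counts with dropout and
planted fold changes, interaction priors with decoy edges, and multichannel
images with analytic ground truth, so the whole pipeline is testable without
any external data.

## The model

Counts are normalized per cell: `x = log2(count / total * 10^4 + 1)`.
For every gene and every (cell type, sample) stratum, expression in the
stratum (foreground) is compared against all remaining cells pooled
(background) with a two-part *hurdle* test suited to zero-inflated
single-cell data:

- a binomial likelihood-ratio test on the detection rate (x > 0), and
- a Gaussian likelihood-ratio test on the positive values,

with the two LR statistics summed and referred to χ² with one degree of
freedom per fitted component. Fold changes are computed on the linear scale
with a pseudocount, `log2FC = log2(mean(2^x_fg − 1) + 1) − log2(mean(2^x_bg − 1) + 1)`,
and p-values are Benjamini–Hochberg adjusted over all (gene, cell type,
sample) tests as one family.

For each prior edge (L → R) and each sample, the interaction score is

```
RL-score = log2(FC_ligand × FC_receptor) = log2FC_ligand + log2FC_receptor
```

with ligand statistics taken in the sender type and receptor statistics in
the receiver type. An edge is flagged **significant** only when, in *every*
sample of the group: both adjusted p-values < 0.01, ligand log2FC ≥ 0.5, and
receptor log2FC > 0.

## Worked example

```r
library(tmekit)

design <- rl_study_design(cells_per_type_per_sample = 200, seed = 1)
sim    <- simulate_counts(design$config)
prior  <- simulate_interaction_prior(design$config, design$true_edges, n_decoys = 20)
res <- run_rl_pipeline(sim$counts, sim$annotation, prior,
                       sender_type = "CAF1", receiver_types = "tumor",
                       group_id = "AOMDSS", qc = design$qc)
head(subset(res$records$tumor, level == "group",
            c(ligand, receptor, rl_score, ligand_log2fc, receptor_log2fc, significant)))
#>     ligand receptor rl_score ligand_log2fc receptor_log2fc significant
#> 4  gene001  gene004   3.1077       1.54756          1.5601        TRUE
#> 8  gene002  gene005   3.1741       1.52686          1.6472        TRUE
#> 12 gene003  gene006   3.0187       1.55391          1.4647        TRUE
#> 16 gene010  gene042  -0.4487      -0.30272         -0.1460       FALSE
#> 20 gene045 mt-gene04 -0.2871      -0.17304         -0.1140       FALSE
#> 24 gene007 mt-gene03 -0.5610      -0.19905         -0.3619       FALSE
```

The three planted ligand→receptor pairs (both partners up-regulated 4-fold
in CAF1 and tumor cells of the AOMDSS group) are recovered with group-mean
RL-scores around 3.1 — the per-sample ligand and receptor log2 fold changes
of ≈1.55 are the planted effect of 2 attenuated by the pooled background,
which itself contains same-type cells from the other samples of the group
(see the vignette) — and every decoy edge scores near zero and is unflagged.

Image quantification on a noisy synthetic image (signal 100, noise sd 10,
threshold 50):

```r
study_mxif_recovery(background_noise_sd = 10, seed = 1)[c("truth", "recovered")]
#> $truth
#>   CAF1   CAF2
#> 0.2500 0.0709
#> $recovered
#>   CAF1   CAF2
#> 0.2500 0.0709
```

and a two-group abundance comparison:

```r
str(compare_groups(c(0.21, 0.25, 0.28, 0.30, 0.26), c(0.10, 0.12, 0.09)))
#> $ t_stat: num 7.38
#> $ df    : num 6
#> $ p     : num 0.000317
```

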