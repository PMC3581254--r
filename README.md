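# ctxflex — structural-context flexibility profiles for catalytic-residue prediction

`ctxflex` identifies enzyme catalytic residues from a single protein
structure, using no homology information. The premise: catalytic residues
sit in structurally rigid surroundings, and the rigidity of a residue's
*context* — its sequence and spatial neighbours — separates catalytic from
noncatalytic positions better than the residue's own crystallographic
B-factor.

The package is aimed at structural bioinformaticians who want per-residue
flexibility/packing profiles from PDB files, and at anyone benchmarking
structure-based functional-site predictors.

## The method

For a chain represented by C&alpha; coordinates, the weighted contact
number of residue *i* is

    D_i = Σ_{j≠i} 1 / r_ij²       (Å⁻²)

a packing density (high = buried, rigid). Its inverse behaves like a
B-factor. Two context profiles average inverse WCN over neighbourhoods:

* **SEQ(n)** — over the sequence window *i−n … i+n* (default n = 1);
* **STR(cutoff)** — over all residues strictly within a distance cutoff
  (default 3 Å), the residue itself included.

SEQ, STR and the experimental B-factor are z-normalized within each protein
(`Z_SEQ`, `Z_STR`, `Z_B`); catalytic residues concentrate at the low (rigid)
end of `Z_SEQ`/`Z_STR`. These profiles — optionally with a 20-bit amino-acid
encoding and a PSI-BLAST conservation score — feed a C-SVC/RBF classifier
trained on balanced subsamples (all catalytic residues plus an equal random
draw of noncatalytic ones) under protein-level 5-fold cross-validation, with
cost/gamma tuned by inner CV on the Matthews correlation coefficient.
Performance is reported as balanced-mode sensitivity/specificity/MCC and as
a per-protein-averaged ROC curve. See `vignettes/ctxflex-methods.Rmd` for
the full account.

## Worked example

A synthetic benchmark with known ground truth: 20 collapsed 100-residue
C&alpha; chains, each with 3 "catalytic" residues planted in rigid contexts
(lowest decile of `Z_SEQ`), B-factors a noisy affine image of inverse
packing.

```r
library(ctxflex)

ds <- make_dataset(20, synthetic_spec(), seed = 42)

# flexibility profile of one chain: planted sites are rigid by construction
pr <- chain_profile(ds$chains[[1]], n = 1, cutoff = 3)
subset(as.data.frame(pr), is_catalytic,
       select = c(res_seq, aa, z_seq, z_str, z_b))
#>    res_seq aa z_seq z_str     z_b
#> 1        1  C -1.15 -1.32 -1.8512
#> 13      13  F -1.49 -1.31 -0.0932
#> 34      34  F -1.35 -1.42  0.7407

# cross-validated catalytic-residue prediction from the SEQ profile alone
tab <- build_feature_table(profile_dataset(ds$chains), "SEQ")
res <- evaluate_protocol(tab, svm_config(seed = 42))
res
#> <evaluation_result> [SEQ] balanced sens = 0.967, spec = 0.900, MCC = 0.869;
#>                     per-protein ROC AUC = 0.957

head(rank_report(res$predictions), 3)
#>     protein residue res_seq rank prob
#> 25 SYN001:A      C1       1   10 0.47
#> 26 SYN001:A     F13      13    1 0.80
#> 27 SYN001:A     F34      34    5 0.76
```

The planted residues carry strongly negative `Z_SEQ`/`Z_STR` (rigid context)
while their `Z_B` values scatter — the B-factor is the noisier signal, and a
classifier trained on `Z_B` alone scores far lower (MCC ≈ 0.2 on the same
benchmark). `rank_report()` lists, for every catalytic residue, its rank
among its own protein's residues by predicted catalytic probability.

Real structures go through the same pipeline:

```r
ch  <- read_chain("1BWZ.pdb", chain = "A")
ch  <- apply_labels(ch, read_labels("sites.tsv", "tsv"))
pr  <- chain_profile(ch, n = 1, cutoff = 3)
```

A thin command-line front end (`exec/ctxflex`) exposes `profile`, `synth`,
`train` and `predict` subcommands over TSV files.

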