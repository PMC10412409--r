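# hashmix

Demultiplexing of hashtag-oligonucleotide (HTO) barcoded single-cell
RNA-seq data with negative binomial regression mixture models.

## What problem this solves, and for whom

When cells from several samples are tagged with sample-specific HTOs and
pooled before droplet-based scRNA-seq, every droplet must afterwards be
assigned back to its sample of origin. Ambient background reads make every
droplet weakly positive for every HTO, multiplets carry signal from two or
more samples, and naive thresholding either discards usable cells or lets
misassigned ones contaminate downstream analysis. `hashmix` is for anyone
with a droplets × HTOs count matrix (plus the RNA library or a
detected-genes vector) who wants probabilistic droplet assignments with
explicit error control.

## The model

For each HTO $j$ the counts follow a two-component negative binomial
mixture — component 1 background, component 2 tagged cells:

$$ f(y_{i,j}) = \sum_{k=1}^{2} \pi_k\, h\!\left(y_{i,j} \mid \mu_{i,k},
\nu_k\right), \qquad \mu_{i,k} = \exp\!\big(\alpha_k + \beta_k \log x_i\big), $$

where $x_i$ is the number of detected genes in droplet $i$ — HTO counts
rise with droplet RNA content, and modelling that association sharpens the
component separation. Parameters are fitted by EM (weighted NB regression
via Fisher scoring with ML dispersion in the M-step); three variants
(regression in both / only the positive / neither component) are fitted
per HTO and the one minimizing the expected number of MAP classification
errors is kept. Per-droplet posteriors are combined across HTOs into a
joint probability; droplets below the acceptance threshold
$p_\mathrm{acpt}$ (default $0.9^n$) are labelled `uncertain`, the rest
`SSD` (single-sample droplet), `MSM` (multi-sample multiplet) or
`negative`. A per-HTO overlap score (shared probability mass of the two
fitted components, in $(0,1]$, small = clean) quantifies data quality.
Single-HTO designs (one tagged sample pooled with untagged cells) are
fully supported.

## Worked example

Simulate a 4-sample pool, inject 100 artificial doublets, halve the tagged
signal to emulate a moderate-quality library, then demultiplex and score:

```r
library(hashmix)
sim    <- generate_dataset(m = 2000, n = 4, seed = 42)
merged <- merge_doublets(sim$experiment, sim$truth, n_doublets = 100, seed = 42)
hx     <- attenuate_signal(merged$experiment, merged$truth, s = 0.5)
res    <- demux(hx, seed = 42)
print(res)
```

```
demux_result: 2100 droplets, 4 HTOs, p_acpt = 0.6561

     MSM negative      SSD
     207      107     1786

per-HTO quality:
  hto  variant          ovs    pi_pos converged
 HTO1     full 6.572432e-05 0.2644958      TRUE
 HTO2 pos_only 1.243584e-04 0.2678954      TRUE
 HTO3 pos_only 2.502288e-04 0.2519021      TRUE
 HTO4     full 1.237720e-04 0.2491395      TRUE
```

Every droplet gets a class, the assigned HTO(s) and the joint probability
that the whole assignment is correct (`res$assignments`); `ovs` near zero
says the background and tagged components barely overlap, i.e. the HTO
data are clean. Scoring against the known truth:

```r
benchmark_metrics(res$assignments, merged$truth)
```

```
precision_SSD 0.9989  sensitivity_SSD 1.0000  F_SSD 0.9994
precision_MSM 1.0000  MSM proportion 0.0986
```

So at half signal strength, 99.9% of droplets called as singlets are
assigned to the right sample and no true singlet is lost; the two errors
are doublets mistaken for singlets.

## Command line

```sh
Rscript inst/scripts/hashmix simulate --m 2000 --n 4 --doublets 100 \
    --seed 42 --out-dir sim/
Rscript inst/scripts/hashmix demux --counts sim/ --genes sim/genes.tsv \
    --seed 42 --out-dir out/            # assignments.tsv, quality.tsv, ...
Rscript inst/scripts/hashmix benchmark --assignments out/assignments.tsv \
    --truth sim/truth.tsv --out metrics.json
```

Each run writes `run_config.json` next to its outputs; same config + seed
reproduces outputs byte for byte.

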