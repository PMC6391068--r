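# enscircuit

Circuit analysis of the enteric nervous system (ENS) from calcium imaging,
gut-motility maps and morphometry.

The package is aimed at researchers studying how myenteric neurons of the
large intestine are functionally wired. Its core measurement is the
**response signature**: a neuron stimulated twice through a focal electrode
on an interganglionic fiber tract is summarized by its Ca²⁺ transient
amplitudes ΔF/F₀ per stimulus and by their ratio

    r = (ΔF/F₀)_ES2 / (ΔF/F₀)_ES1,

which classifies it as *blocked* (Type I, responded to ES1 only), *reduced*
(II, r < 0.8), *unchanged* (III, 0.8 ≤ r ≤ 1.2), *increased* (IV, r > 1.2)
or *new* (V, responded to ES2 only). Around the fingerprint sit:

* spatial mapping of responder classes relative to the electrode
  (aboral fractions, the ±250 µm electrode band, soma-size morphometry with
  the strict >200 µm² large-cell filter);
* spatiotemporal diameter maps of colonic motility with detection of
  migrating motor complex (CMMC)-like propagating contractions;
* the monosynaptic wiring model: each stimulated fiber activates
  `fanout = 2` neurons (one antidromic, one synaptic), compared against
  regional neuron-density (#N), fiber (#F) and responder (#R) counts;
* a two-component Gaussian mixture of axonal projection lengths whose
  density trough splits short- from long-projecting neurons, with χ²
  comparison of regional orientation proportions;
* voxel-based surface-to-surface contact between soma and varicosity masks
  in 3D stacks.

A synthetic-data module generates every input the pipeline consumes -
movies, diameter maps, projection tables, contact phantoms - together with
ground truth, so every estimator is validated by parameter recovery. See
`vignettes/enscircuit-methods.Rmd` for the full model description.

## Worked example

```r
library(enscircuit)

gm <- generate_movie(sim_movie_config(), seed = 1)  # 60 neurons, 2 epochs
gm$movie
#> <recording_movie> 260 x 340 px, 160 frames @ 2 Hz, 5 um/px, 2 stim epoch(s)

fp <- fingerprint_pipeline(gm$movie, gm$truth$rois)
table(fp$signatures$cls)
#>   I  II III  IV   V
#>   1  13  30  13   3

class_accuracy(gm$truth, fp$signatures)
#> [1] 1
```

On this noise-free movie the pipeline recovers every neuron's true class:
one blocked neuron, a majority of unchanged responders centered on ratio 1
(the 0.2-wide histogram bins `[0.8,1.0)` and `[1.0,1.2)` hold 26.7% and
23.3% of neurons), and three "new" cells.

The wiring arithmetic runs off regional counts alone:

```r
consistency_report(colon_wiring_counts())
#> <wiring_report>
#>   neuron ratio dis/prox : raw 0.847, reported 0.85
#>   fiber ratio dis/prox  : raw 0.507, reported 0.50
#>   expected responder ratio: raw 42.9%, reported 42.5%
#>   observed responder ratio: 33.2%
#>   model (fanout 2): predicted prox 72 / dis 36, observed 123.5 / 41
#>   excess observed/predicted: prox 1.72, dis 1.14
```

The observed distal/proximal responder ratio (33%) is lower than neuron
density and fiber counts alone would predict (42.5%), and the proximal
colon activates 1.7× more neurons than the two-per-fiber model allows -
the quantitative signature of denser proximal wiring.

## Command line

A thin front-end over the same functions ships at
`inst/cli/enscircuit.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","enscircuit.R",package="enscircuit"))') \
  simulate --kind movie --seed 1 --out-dir sim/
```

Subcommands: `simulate`, `fingerprint`, `spatial`, `motility`,
`projections`, `contact`, `report`; all accept `--config` (YAML/JSON, see
`run_config()`), `--seed` and `--out-dir`.

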