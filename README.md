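# synaptica

Single-synapse colocalization and spatial-interaction analysis for
punctate immunofluorescence, in R.

## What it is for

Studies of synapse composition image tissue with several immunolabels — a
presynaptic scaffold (bassoon), a postsynaptic scaffold (homer, PSD-95,
SAP102), receptor subunits (e.g. NMDA-receptor GluN2A–D), and vesicular
glutamate transporters (VGLUT1/2) that distinguish input types — and then
ask object-level questions: which fraction of puncta are synaptic, which
synapses carry which receptor subunit, and are two channels spatially
associated at all? `synaptica` implements that pipeline end to end for
single-plane multi-channel images:

* **Puncta detection** — prominence-based maxima detection (the ImageJ
  noise-tolerance convention), marker-seeded watershed segmentation,
  disc median pre-filtering, and calibrated size gates (0.02–5 µm² for
  scaffold markers, 0.05–5 µm² for receptors).
* **Synapse pairing** — a synapse is an overlapping pre/post punctum pair
  (mask intersection ≥ 1 pixel); distances are measured between intensity
  maxima; pairs are gated by VGLUT input type; receptor puncta are
  classified post-/presynaptic with the shortest-distance tie-break.
* **Spatial interaction** — an object-based nearest-neighbor analysis: the
  observed NN-distance density q(d) is modeled as the context density p(d)
  tilted by a Hernquist pairwise potential,

      q̂(d) = p(d) · exp(ε σ / (d + σ)) / Z,

  where ε is the dimensionless interaction strength (0 = independence,
  positive = attraction) and σ a length scale in nm; significance comes
  from a Monte Carlo randomization test (reference coordinates redrawn,
  add-one p-value, α = 0.05).
* **Aggregation** — per-FOV metrics averaged per mouse (mice are the unit
  of analysis) and Welch's unequal-variance t-test between groups.
* **Synthetic data** — a ground-truthed generator (Gaussian-PSF puncta
  fields with sub-resolution pairing offsets, input-gated receptor
  attachment, VGLUT terminal masks, and Gibbs point patterns with known
  ε/σ) so every stage is testable without external data.

## Worked example

Simulate a field, run the analysis, and test the pre/post association:

```r
library(synaptica)

cfg <- synth_config(seed = 7)              # 512x512 px, 27 nm/px defaults
gt  <- generate_synapse_field(cfg)         # ground truth tables
imgs <- render_ground_truth(gt)            # pre/post/receptor/VGLUT images

res <- run_fov_analysis(imgs, default_pipeline_config(interaction_runs = 199))
subset(res$metrics, metric %in% c("pct_pre_synaptic", "pct_post_synaptic",
                                  "pct_synapses_receptor_post"))
res$interaction[["pre~post"]]
```

which prints

```
                       metric    value numerator denominator
1            pct_pre_synaptic 44.82759        52         116
2           pct_post_synaptic 44.53782        53         119
10 pct_synapses_receptor_post 41.81818        23          55
<interaction_fit> epsilon = 7.414, sigma = 1328.6 nm, residual = 0.0166
  Monte Carlo: p = 0.005 (199 runs, alpha = 0.05) -> reject independence
```

Read: 45% of presynaptic and 45% of postsynaptic puncta were detected as
synaptic (52 of 116 and 53 of 119); 23 of the 55 detected synapses carry a
postsynaptic receptor punctum (this field was generated with attachment
probability 0.51); and the pre/post channels show a strong positive
interaction that the randomization test calls significant at the smallest
achievable p-value for 199 runs. Rotating one channel by 90°
(`rotate_channel_control()`) destroys the association and the test stops
rejecting.

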