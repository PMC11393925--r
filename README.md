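# channelpat

Channel-rank feature engineering and interpretable classification for
multi-channel EEG.

Many EEG classification pipelines work on amplitudes, spectra, or local
signal patterns. `channelpat` instead works on the *relative ordering of the
channels*: which electrode is most active right now, which comes second, and
how that ordering hands over from one instant to the next. Because channel
ranks are invariant to any monotone rescaling of the amplitudes, the features
are robust to gain differences and directly interpretable in terms of scalp
topography. The package targets researchers who classify fixed-length EEG
segments (two or more classes) and want a lightweight model whose decisions
can be read back as interactions between brain lobes.

## The method

For a segment `X` with `C` channels and `N` samples:

1. **Channel-rank transform.** At each time point `t` the channels are
   sorted by descending amplitude and their indices emitted, turning `X`
   into a flat sequence `CS` of length `C·N` in which every aligned block of
   `C` entries is a permutation of `1..C`.
2. **ChannelPat histogram.** Every overlapping pair `(CS[t], CS[t+1])` is
   coded as the two-digit base-`C` number `C·(a−1) + (b−1)` and the codes
   are tabulated into a `C²`-bin histogram of raw transition counts
   (`C = 14` gives the canonical 196 features). The counts sum to `C·N − 1`.
3. **INCA selection.** Neighborhood component analysis assigns each feature
   a relevance weight by maximizing the softmax leave-one-out
   nearest-neighbor objective; prefixes of the descending-weight ranking
   (sizes 10..196 by default, 187 candidates) are scored by stratified
   10-fold CV of a 1-NN loss classifier and the most accurate prefix wins.
4. **tkNN classification.** A grid of 60 kNN configurations
   (`k = 1..10` × {L1, L2} × {equal, inverse, squared-inverse} weights)
   produces 60 cross-validated prediction vectors; sorting them by accuracy
   and taking the elementwise mode of the top `q` for `q = 3..60` adds 58
   iterative-majority-voting outcomes; a greedy pass keeps the most accurate
   of the pooled 118.
5. **Lobish interpretation.** Each selected feature encodes an ordered
   channel pair; mapping both channels through a channel→lobe lookup table
   (F frontal, T temporal, P parietal, O occipital) yields a two-symbol
   word, and the concatenated "sentence" is summarized by symbol histograms,
   a 4×4 transition matrix, and Shannon entropies (bounded by log₂4 = 2 and
   log₂16 = 4 bits).

## Worked example

```r
library(channelpat)

d   <- synth_eeg_dataset(effect = 1.0, noise_sd = 0.05,
                         segments_per_class = 30, n_samples = 128, seed = 13)
fit <- channel_model(d, seed = 13)
fit
#> channel-rank EEG classification model
#> call: channel_model(x = d, seed = 13)
#> segments: 60, features: 196 -> 10 selected, seed 13
#> final CV accuracy: 1.0000 (kNN config 1)

rep <- lobish(fit)
rep$symbol_counts
#>  F  T  P  O
#> 14  3  3  0
sprintf("%.4f / %.4f bits", rep$symbol_entropy_bits, rep$transition_entropy_bits)
#> [1] "1.1813 / 2.0346 bits"

fit$metrics
#> accuracy (global): 100.00%
#>    class sensitivity specificity precision  f1 geometric_mean
#>        A         100         100       100 100            100
#>        B         100         100       100 100            100
#>  overall         100         100       100 100            100
```

The synthetic generator plants opposite channel-gain orderings in the two
classes, so the rank histograms separate cleanly and the pipeline recovers
the labels perfectly; the ten selected features decode to a 20-symbol Lobish
sentence dominated by frontal channels of the default 14-channel montage.
Held-out segments from the same generator are labeled by
`predict(fit, new_data)`.

A thin command-line front end over the same functions ships in
`inst/cli/channelpat` (subcommands `synth`, `transform`, `extract`,
`select`, `classify`, `lobish`, `run-all`).

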