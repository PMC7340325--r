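# Bundled fixtures

Synthetic stand-in histograms for the filopodium length (um, mean 17) and
angle (degrees, relative to the tissue-ward axis) distributions, generated
by `make_fixture("histograms")`. They emulate the *shape* of measured
cytoneme distributions (Gamma-like lengths, centred truncated-Normal-like
angles) but are not measured data. Format: two tab-separated columns
(`bin_center`, `weight`), loadable with `read_histogram_dist()`.
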