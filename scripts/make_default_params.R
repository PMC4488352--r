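#!/usr/bin/env Rscript
# Regenerates the packaged default score constants
# (inst/extdata/default_score_params_synthetic.json) by calibrating on the
# packaged synthetic corpus: 50 noisy canonical alpha-helical traces
# (12 atoms, sigma = 0.05 A, seeds 1..50). Run from the repository root.
library(helixfit)

specs <- calibration_corpus_specs()
fits <- lapply(specs, function(s) helixfit(generate_fixture(s)))
params <- calibrate_score_params(fits)
print(params)
write_score_params(params,
                   "inst/extdata/default_score_params_synthetic.json")
cat("wrote inst/extdata/default_score_params_synthetic.json\n")
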