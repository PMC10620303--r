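#!/usr/bin/env Rscript
# Regenerates the packaged fixture parameter sets from their recorded seeds.
# Run from the repository root:  Rscript scripts/make_fixtures.R
suppressPackageStartupMessages(library(mgturing))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

gen <- search_admissible(seed = 20260930, mode = "general", max_tries = 2000)
print(gen)
save_params(gen$params, "inst/extdata/fixture_general.json")

sym <- search_admissible(seed = 20260930, mode = "symmetric",
                         max_tries = 2000)
print(sym)
save_params(sym$params, "inst/extdata/fixture_symmetric.json")
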