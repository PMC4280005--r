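# Drop-in slot for original reference data

This directory is a placeholder for the original batch-study data files
that cannot be redistributed with the package. To enable the reproduction
test in `tests/testthat/test-acceptance.R`, place here:

- `measurements_145.csv` — columns `time`, `output_id`, `mean`, `sd`
  (the measurement realization used with free fluxes 1, 4, 5)
- `network.tsv` / `annotation.tsv` — the network in the package's TSV
  format (see `read_network()`)

and reinstall the package. Without these files that single test reports a
failure by design; all bundled analyses use the synthetic reconstructions
in `R/synthetic.R` instead.
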