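Package: circuitmap
Title: Causal Brain-Circuit Mapping from Lesions and Stimulation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping brain circuits that are causally linked to a
    clinical outcome from focal perturbations (lesions, transcranial magnetic
    stimulation sites, deep brain stimulation fields). Perturbation sites are
    seeded against a resting-state connectome to obtain whole-brain Fisher-z
    connectivity maps, which are related to outcomes by voxel-wise partial
    correlation controlling for nuisance variables (depression, lesion size,
    baseline severity). Dataset-level circuit maps are combined by weighted
    means, tested by outcome-shuffle permutation (spatial-correlation and
    max-statistic family-wise-error peak tests), and validated out-of-sample
    by scoring held-out stimulation sites (connectivity or overlap) against
    leave-one-dataset-out circuits. Includes a minimal NIfTI-1 reader/writer
    and a synthetic-data generator (spatially autocorrelated multi-subject
    connectome, planted circuit, confounded cohorts) so the whole pipeline is
    testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
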