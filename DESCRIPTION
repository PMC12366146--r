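Package: wmhnet
Title: Lesion Network Damage from White Matter Hyperintensities
Version: 0.1.0
Authors@R: person("wmhnet", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies regional structural disconnection (ChaCo, "change of
    connectivity") caused by white matter hyperintensity and stroke lesion
    masks projected onto a reference streamline connectome, partitions
    hyperintensity masks into periventricular and deep components by a
    distance threshold to the ventricles, and relates dichotomized regional
    disconnectivity to an ordinal clinical outcome through covariate-adjusted
    proportional-odds models with false-discovery-rate control. Includes a
    seeded synthetic-data generator (toy atlas, streamline connectome,
    patient lesion masks, proportional-odds outcomes) so the full pipeline
    runs and is testable at desk scale, plus NIfTI/TCK readers and writers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    numDeriv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
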