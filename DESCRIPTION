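Package: wristdecon
Title: Deconvolution of Wrist Motor Commands from Muscle Activity and
    Movement Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the composition of motor commands at the wrist from
    surface electromyography (EMG) of the four wrist prime movers and wrist
    kinematics. A linear viscoelastic joint model links normalized muscle
    tensions to position-, velocity- and acceleration-proportional torque
    components; the velocity-to-position weight ratio (B/K) is identified per
    task by uncentered canonical correlation analysis and by an exhaustive
    grid search with sign-constrained least squares. Includes EMG envelope
    extraction and tension normalization, cosine-fit preferred directions and
    agonist analysis, exact Mann-Whitney group comparisons, a model-consistent
    synthetic-trial generator for step-tracking and pursuit tasks, and a
    command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
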