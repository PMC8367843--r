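Package: rnngeom
Title: Rate Recurrent Networks and Population Geometry for
    Context-Dependent Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains continuous-time rate recurrent neural networks on a
    delayed context-dependent sensory-integration task and provides a
    geometric analysis toolbox for the resulting population dynamics:
    epoch-wise principal-component subspaces, task-related axes and
    axis-subspace angles, trajectory kinematics, mixed-selectivity
    classification, sequentiality index with Monte Carlo controls,
    rotational (jPCA-style) dynamics via skew-symmetric fits and polar
    decomposition, fixed-point and line-attractor analysis, and
    recurrent-weight perturbation experiments. Training uses
    backpropagation through time with Adam, implemented natively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
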