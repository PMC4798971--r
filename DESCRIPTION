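Package: racecom
Title: Correlated Race Models of Choice, Confidence, and Changes of Mind
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analytic and simulation tools for bounded evidence-accumulation
    accounts of perceptual decisions reported together with a confidence
    rating. Implements the method-of-images solution for a race between two
    negatively correlated accumulators with absorbing bounds, the mapping
    from decision state and elapsed time to the log-odds that the choice is
    correct, a post-initiation processing stage that produces changes of
    mind about direction and confidence, two-stage maximum-likelihood
    fitting to choice/confidence counts and reaction times, synthetic
    generators for trials, reach trajectories and random-dot movies,
    motion-energy filtering with psychophysical kernels, and the behavioral
    analyses (trajectory-based change detection, logistic models,
    confidence-accuracy odds ratios, points accounting) used to study the
    apparent dissociation between confidence and accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
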