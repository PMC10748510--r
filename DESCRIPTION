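Package: textcontours
Title: Interpretable Text Contours and Explainable Mental-Health Text Classification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window "text contour" extraction of interpretable
    linguistic features (morpho-syntactic complexity, lexical richness,
    readability, cohesion, register stylistics, and lexicon-based affect and
    emotion scores), sequence classifiers over those contours (a BiLSTM and a
    compact attention encoder with multi-task emotion/personality fusion), and
    a layered explanation suite: LIME, submodular-pick LIME group importance,
    attention-gradient attribution (AGRAD), and lexicon-category coverage of
    top-ranked words. Includes a fully deterministic synthetic-corpus
    generator with planted signal so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
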