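Package: pressanx
Title: Seated-Pressure Analysis of Driver Anxiety
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting driver anxiety from seat-pad and
    backrest pressure-mat recordings. Segments 32x32 pressure frames into six
    anatomical regions and extracts the 36-variable regional feature set
    (average pressure, contact area, centre of pressure, and their shares),
    extracts 50-frame event-anchored windows around annotated driving
    scenarios, screens paired anxious-vs-calm statistical features with a
    Lilliefors-gated paired t / Wilcoxon signed-rank test and effect sizes
    (paired Cohen's d, matched-pairs rank-biserial r), and scores driving
    scenarios by cosine similarity between dynamically baseline-corrected
    scenario difference vectors and the static anxiety prototype. Includes a
    synthetic seated-pressure study generator with planted regional, temporal
    and scenario structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
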