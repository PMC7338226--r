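Package: meagent
Title: Moral Emotional Agents and Emotion-Understanding Scores for Narrative Scenarios
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates story characters as belief-desire-intention agents with
    OCC-style emotional appraisal and explicit moral values (the Moral
    Emotional Agent). Agents monitor values, adopt goals, rank plans by an
    expected emotional reward, execute them, and derive emotions (including
    compound moral emotions such as remorse and gratification) from appraisal
    variables. Ships machine-readable encodings of seven narrative scenarios
    from two emotion-understanding tests (Actor Studio and Audience Studio)
    together with the published per-emotion selection percentages of a
    traumatic-brain-injury group and matched controls. Reconstructs integer
    selection counts from the printed marginals, generates synthetic
    respondent matrices consistent with them, and computes the full scoring
    battery: emotion/error scores over a moral and a non-moral emotion
    partition, Simple Matching Coefficients, Mann-Whitney tests with exact
    permutation p-values, and Spearman rank correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
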