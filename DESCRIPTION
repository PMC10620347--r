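Package: stratclass
Title: Classification of Participation-Focused Caregiver Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reusable pipeline for multinomial classification of short
    free-text caregiver strategies into participation-related construct
    classes (environment/context, sense of self, preferences, activity
    competence, non-strategy). Implements deterministic text preprocessing
    (spelling correction by edit distance, entity placeholders,
    lemmatization), TF-IDF and paragraph-vector document representations,
    hand-engineered feature blocks (part-of-speech and dependency tag
    counts, PMI-selected likely word sets, concept-lexicon features), four
    classical classifiers (majority baseline, multinomial naive Bayes,
    logistic regression trained by SGD, linear SVM), flat and cascaded task
    designs, stratified splitting with largest-remainder allocation,
    repeated stratified 10-fold cross-validation, and macro-averaged
    evaluation. Ships a calibrated synthetic-corpus generator so every
    stage is exercisable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), e1071, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
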