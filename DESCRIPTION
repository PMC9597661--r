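Package: smilesbert
Title: Masked-Language-Model Transformer Fingerprints for SMILES
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale toolkit for learning molecular fingerprints from
    SMILES strings with a RoBERTa-style transformer encoder. Covers corpus
    curation (canonicalization, frequency-driven augmentation, seeded
    shuffling), raw-stream unigram subword tokenization, masked-language-model
    pre-training with gradient accumulation, mean- and [CLS]-pooled
    fingerprint inference, single-head and Siamese fine-tuning, virtual
    screening evaluation (AUCROC, BEDROC), clustering-based fingerprint
    quality assessment, and attention-to-functional-group attribution.
    Synthetic SMILES generators make every component testable without any
    external chemical database. Chemistry primitives (canonicalization,
    randomized SMILES traversal, substructure matching) are delegated to
    RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    cluster,
    e1071,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with rdkit, on PATH as 'python'
Config/testthat/edition: 3
RoxygenNote: 7.3.3
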