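Package: retroformer
Title: Attention-Based Sequence Translation for Single-Step Retrosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats single-step retrosynthesis as machine translation over
    SMILES strings: an attention-only (transformer) encoder-decoder is trained
    to map a product molecule, optionally prefixed with a reaction-class token,
    to ranked reactant sets decoded by beam search. Includes atom-level SMILES
    tokenization, reaction dataset handling, token-budget batching, checkpoint
    averaging, a template-based synthetic reaction generator for end-to-end
    testing, and an evaluation suite covering canonical-match top-N accuracy,
    grammatical-invalidity analysis, ring-system and protecting-group failure
    categorization, and annotation-corrected ("true") accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
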