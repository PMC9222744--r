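Package: nedsem
Title: Neutrosophic-Entropy Segmentation of Dermoscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unsupervised segmentation of pigmented skin-lesion (dermoscopy)
    images built around a single-valued neutrosophic entropy. Each RGB channel
    is mapped to a neutrosophic (truth, indeterminacy, falsity) triple using
    flat grayscale morphology (closing for truth/falsity, morphological
    gradient for indeterminacy), collapsed to a per-pixel entropy map via an
    isentropic-cylinder entropy model, combined into a red-minus-blue entropy
    difference feature, and clustered with an MRF-regularised hierarchical
    Gaussian mixture model fitted by EM. Includes a seeded synthetic-lesion
    generator with ground-truth masks, confusion-matrix evaluation metrics
    (accuracy, specificity, Jaccard, Dice), K-means and fuzzy C-means
    comparator clusterers, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    grDevices,
    graphics,
    jpeg,
    png,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
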