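Package: wsiMIL
Title: Attention-Based Multiple Instance Learning for Whole-Slide-Image
    Classification and Region-of-Interest Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Weakly supervised classification of whole slide images (WSI)
    with attention-based multiple instance learning (MIL). Implements three
    permutation-invariant MIL heads -- classical attention pooling (AMIL),
    additive per-patch scoring (AdMIL), and a hybrid that combines the
    additive head with tanh attention -- together with the full training and
    evaluation protocol (stratified 80/20 split, 5-fold cross-validation,
    Adam with optional cosine annealing, AUROC on a held-out test set).
    Includes a WSI tile preprocessing pipeline (Otsu tissue masking,
    artifact color filtering, pyramid coordinate mapping, tile padding,
    tissue-fraction filtering, fractional and K-means cluster sampling), an
    HDF5 embedding store with HED stain augmentation, slide-painting
    heatmaps of attention and excitatory/inhibitory patch contributions,
    and synthetic generators for MIL bags and slide images so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    rhdf5,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC
biocViews: Classification, Pathology, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'synthetic-bags.R'
    'utils.R'
    'wsi-prep.R'
    'embedding-store.R'
    'heatmap.R'
    'mil-model.R'
    'mil-train.R'
    'synthetic-slide.R'
    'wsiMIL-package.R'
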