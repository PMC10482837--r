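Package: limbalign
Title: Lower-Limb Alignment Measurement from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Measures frontal-plane lower-limb alignment from per-bone binary
    segmentation masks of full-leg radiographs. Detects anatomical landmarks
    (femoral head centre, joint orientation lines, mid-diaphyseal axes) with
    classical image-processing operators, constructs mechanical and anatomical
    axes, and computes the sixteen Paley-style alignment parameters (mLPFA,
    mLDFA, mMPTA, mLDTA, MAD, mJLCA, mTFA, aMPFA, aLDFA, NSA, aMPTA, aLDTA,
    aTFA and three lengths) with normal-range classification. Includes a
    parametric leg-phantom generator with closed-form ground truth for
    end-to-end validation, deterministic preprocessing operators (padding,
    resizing, CLAHE, ROI cropping, side flipping), and an evaluation suite:
    Dice and Hausdorff segmentation metrics, COCO-style mean average precision,
    and method-comparison statistics (Lin's concordance correlation,
    Pearson correlation, ICC(2,1), Bland-Altman limits of agreement, error
    indices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
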