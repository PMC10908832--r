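Package: niistego
Title: Slice-Embedding Compression of NIfTI MRI Volumes by Quantization
    Hiding
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Halves the slice count of 3-D NIfTI-1 magnetic resonance
    volumes by embedding each odd slice into the 4x4 block DCT detail
    coefficients of its preceding even slice using quantization index
    modulation, and blindly reconstructs the embedded slices from the
    stego file alone. Provides the full codec (normalization, block
    transform, interval quantization embedding/extraction, median
    post-filter), volume-level pipelines with self-describing header
    metadata, image-quality metrics (PSNR, SNR, SSIM, histogram entropy,
    bit error rate, five-number summaries), and a deterministic MRI-like
    phantom generator for reproducible evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
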