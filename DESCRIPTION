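Package: lcmqsm
Title: Latent-Code Modulated Convolutional Networks for Quantitative
    Susceptibility Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative susceptibility mapping (QSM) at desk
    scale: the k-space dipole forward model, thresholded k-space division
    (TKD) pre-estimation, multi-orientation (COSMOS) least-squares
    inversion, a synthetic brain-phantom generator with linear
    amplification and spherical susceptibility sources, and a latent-code
    modulated convolutional network (LCMnet) that fuses field, magnitude
    and pre-estimated susceptibility inputs. Includes a patch-based
    training loop with an MSE plus high-frequency error norm (HFEN) loss,
    AdamW optimization, ablation variants, and the PSNR/RMSE/MSSIM/HFEN
    evaluation metrics, with NIfTI input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
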