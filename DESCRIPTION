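Package: ecgbench
Title: Electrical Characterization of Textile ECG Electrodes on a Synthetic Measurement Bench
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the electrical characterization of dry (textile)
    biopotential electrodes against commercial Ag/AgCl references:
    two-configuration skin-electrode contact-impedance decomposition from
    voltage phasors, Lissajous and cross-correlation phase estimation,
    single- and double-dispersion Cole (fractional-order) impedance model
    evaluation and bounded least-squares fitting, area-under-the-curve
    spectral scores, electrode polarization statistics (mean DC level and
    the standard average exchange ratio with interquartile-range outlier
    removal), an ECG FIR filter bank (powerline notches plus cardiac
    bandpass) with noise-power and Pearson similarity metrics, Pan-Tompkins
    QRS detection with full P-Q-R-S-T delineation and a two-channel
    segmentation error rate, and the accompanying statistical comparison
    workflow (normality/homoscedasticity checks dispatching parametric or
    non-parametric tests). A synthetic measurement bench generates every
    input the pipeline consumes: simulated impedance sweeps over known
    circuits, sinusoid pairs with known phase, annotated two-channel ECG
    with controlled corruption, and DC polarization series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    minpack.lm,
    car,
    nortest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr,
    pracma
Config/testthat/edition: 3
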