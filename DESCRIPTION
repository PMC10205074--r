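Package: freqtag
Title: Frequency-Tagged MEG Analysis of Syllable- and Word-Level Speech
    Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frequency-tagging studies of speech processing in
    which isochronous syllables (4 Hz) form disyllabic words (2 Hz). The
    package generates paradigm-faithful stimulus sequences with controlled
    syllable-transition statistics and simulates multichannel trial data
    with known ground truth; it implements syllable-to-syllable
    transitional-probability contrasts, MEG-style preprocessing (filtering,
    z-score and range artifact rejection, epoching, downsampling, trial
    matching), evoked tagging spectra with neighbour-bin contrasts, DICS
    and LCMV beamforming with common spatial filters, cerebro-acoustic
    coherence from a cochlear-filterbank envelope, Gaussian-copula mutual
    information for cross-frequency coupling, and cluster-based Monte
    Carlo permutation statistics with nonparametric ROI tests and a mixed
    ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
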