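Package: pabarcode
Title: Activity Barcoding and Pattern Complexity of Wearable IMU Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multidimensional measurement of habitual physical activity from
    five synchronized body-worn inertial measurement units (trunk, thighs,
    shanks), aimed at children with cerebral palsy but applicable to any
    cohort wearing the same setup. Detects postures from gravity acceleration
    and walking bouts from shank pitch angular velocity, symbolizes each day
    into a 22-state activity barcode combining activity type, bout duration
    and intensity, reduces it to six physical activity states (PAS), and
    quantifies pattern complexity (normalized information entropy, sample
    entropy, Lempel-Ziv complexity, and the composite scores CC and CDS).
    Includes a capacity-linked synthetic cohort generator, the cohort-level
    statistical battery (Spearman/Holm correlation families, age-partialled
    rank correlations, achiever/non-achiever ROC analysis with Youden-optimal
    capacity cut-offs), and a small command-line pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    signal,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
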