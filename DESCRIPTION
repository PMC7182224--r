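Package: sdohmarkers
Title: County-Level Social Determinants of Health Marker Scoring and
    Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores U.S. counties against fifteen binary markers of medical,
    economic, and geographic vulnerability (quantile thresholds on national
    distributions, rurality codes, persistent poverty, and primary care
    Health Professional Shortage Area status), summarizes marker burden
    nationally and by HHS Region, computes conditional marker co-occurrence,
    and ranks the markers contributing most to cross-county variability with
    a from-scratch Multiple Correspondence Analysis.  Includes a calibrated
    synthetic county/HPSA data generator so the whole pipeline runs without
    restricted data downloads, plus a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
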