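Package: farmburden
Title: Economic Burden of Farm Injury Deaths and Workers' Compensation Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the direct economic burden of unintentional
    farm injury deaths and workers' compensation injury claims. Implements a
    per-case human-capital fatality costing model (discounted future earnings
    under an age-dependent full-time-equivalent retirement trajectory,
    household production, a friction period, compensation payouts and fixed
    direct costs, all indexed to a common base year with a consumer price
    index), aggregation of compensation claims over severity, period and
    category axes, and the statistical disclosure-control conventions used to
    publish such surveillance tables (small-cell suppression, complementary
    masking, multiple-based rounding). A synthetic registry generator emulates
    the marginal structure of the restricted coronial and compensation data
    sources so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
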