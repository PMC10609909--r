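Package: cambium
Title: Process-Based Simulation of Conifer Cambial Cell Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the seasonal activity of the vascular cambium in
    conifers as a radial file of dividing cells driven by daily integral
    environmental growth rates. Each cell progresses through the cell-cycle
    phases G1, S, G2 and M by size thresholds, grows in G1 at a Gompertz
    rate controlled by the concentration of a differentiation inhibitor,
    and divides asymmetrically, partitioning its inhibitor between
    daughters. Cells whose inhibitor concentration falls below a threshold
    leave the file for the enlargement zone; the count of such exports over
    a growing season is the simulated annual cell production. The seasonal
    inhibitor supply of the initial cell is predicted from summary
    statistics of the daily growth-rate curve by a linear regression, and a
    calibration harness provides multi-year reconstruction, supply
    inversion by monotone bisection, calibration/verification splits and
    average-season parameter tuning. A synthetic-data generator produces
    growth-rate series and full study fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
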