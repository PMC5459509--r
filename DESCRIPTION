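Package: flybeat
Title: Optical Heartbeat and Intracellular Action Potential Analysis for
    the Drosophila Heart Tube
Version: 0.1.0
Authors@R:
    person("flybeat", "maintainers", email = "flybeat@example.org",
           role = c("aut", "cre"))
Description: Quantification of cardiac function in the semi-intact
    Drosophila heart preparation. Converts high-speed movies of the
    beating heart tube into M-mode kymographs, tracks the heart walls to
    produce calibrated diameter traces, segments beats into diastolic and
    systolic intervals, computes the arrhythmia index, diastolic and
    systolic diameters and fractional shortening, parses individual
    contractions into shortening, isometric and lengthening phases under
    viscous load, extracts action-potential features (resting potential,
    amplitude, peaks per burst, event duration, APD10/50/90, early
    afterdepolarization and burst classification) from intracellular
    recordings, aligns simultaneous optical and electrical recordings via
    a TTL channel, and implements delta-Ct and delta-delta-Ct expression
    arithmetic. A fully parameterized synthetic-data generator with exact
    ground truth supports validation of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
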