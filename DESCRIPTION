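Package: kloss
Title: Potassium Loss and Hyperkalemia in Simulated Acute Myocardial Ischemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled cell and tissue simulation of extracellular potassium
    accumulation during the first 30 minutes of acute myocardial ischemia.
    Implements an ischemia-modified O'Hara-Rudy human ventricular action
    potential model (ATP-sensitive potassium current, metabolic scaling of
    the NaK, sarcolemmal Ca and SERCA pumps, acidosis and
    lysophosphatidylcholine effects on sodium and calcium currents) with a
    dynamic extracellular cleft potassium concentration, embedded in a
    one-dimensional cable with explicit operator-splitting numerics and a
    Nernst-Planck transport equation for extracellular potassium. Analysis
    tools compute per-current potassium flux rates, action potential
    duration and alternans statistics, diastolic potassium minima,
    injury currents, electrograms and ischemic border-zone metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
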