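Package: calciq
Title: Quantitative Cryo-Imaging of Intracellular Calcium Stores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipelines for cryo-imaging of intracellular
    calcium pools in coccolithophore cells. Implements backscattered-electron
    (EsB) grey-level calibration against internal standards via Heinrich
    backscatter coefficients and the mixture rule, inversion of grey values to
    calcium molarity under a Ca:P 1:2 electrolyte model, soft X-ray Ca L-edge
    optical-density difference mapping and concentration estimation with a
    27 M calcite internal standard, Ca K-edge XANES preprocessing and
    constrained linear-combination fitting, even/odd Fourier shell correlation
    resolution estimation, and the cellular calcium-budget arithmetic. A
    synthetic phantom generator renders ground-truthed FIB-SEM and X-ray
    stacks so every stage is verifiable by closed-loop parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
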