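Package: qrechem
Title: Quantum and Classical Resource Estimation for Active-Space
    Electronic-Structure Hamiltonians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the cost of simulating active-space
    electronic-structure Hamiltonians of heme-enzyme (cytochrome P450 type)
    models on fault-tolerant quantum computers and on classical machines.
    Reads and writes FCIDUMP integral files, generates synthetic
    chemistry-like Hamiltonians, and provides a small full
    configuration-interaction oracle.  Implements the three tensor
    factorizations of the two-electron integral tensor used in qubitized
    quantum phase estimation (single factorization, double factorization,
    tensor hypercontraction), their qubitization L1 norms (lambda),
    accuracy-controlled rank selection against a correlated-energy
    criterion, logical resource estimates (Toffoli and logical-qubit
    counts), surface-code physical compilation with spacetime-volume
    configuration optimization, and DMRG classical-cost extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
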