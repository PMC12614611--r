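Package: ppauc
Title: Privacy-Preserving Computation of the Global ROC AUC Across Data
    Stations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements two multi-party protocols for computing the area
    under the ROC curve (AUC) of a binary classifier whose prediction
    scores and labels are distributed across several data stations that
    may not share raw data: an exact, tie-aware protocol (DPPE-AUC) and a
    faster fixed-threshold approximation (DPPA-AUC). Both combine a
    modified Paillier cryptosystem with additively split secret keys
    (proxy re-encryption), hybrid AES-GCM/RSA envelopes, an order- and
    tie-preserving multiplicative score mask with dummy-sample injection,
    and randomized encoding of products, so that a semi-honest proxy can
    aggregate encrypted true/false-positive counts without learning
    labels or raw scores. The package runs the full protocol as a local
    simulation (in one process or via serialized train-state files),
    ships plaintext oracles for verification, and includes generators for
    the synthetic evaluation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    openssl,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
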