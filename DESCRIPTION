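Package: pspgnm
Title: Protein Stability Change Prediction with a Weighted Gaussian Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the unfolding free-energy change (ddG) of single point
    mutations from protein structure alone. A coarse-grained C-alpha Gaussian
    network model is weighted by Miyazawa-Jernigan statistical contact
    energies; partial unfolding is simulated by iteratively breaking the
    residue contact with the largest mean-squared fluctuation in distance, and
    ddG is assembled from rank-matched contacts broken at the mutation site in
    the wildtype and mutant networks. Includes an AAindex matrix parser,
    synthetic-structure fixtures, benchmark-table evaluation metrics
    (Pearson correlation, RMSE, antisymmetry, bias) and parameter scans.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
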