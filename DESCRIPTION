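Package: sornroute
Title: Self-Organized Routing of Stimulus Information in Recurrent Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of self-organizing recurrent networks
    (SORN) of conductance-based leaky integrate-and-fire neurons equipped with
    spike-timing-dependent plasticity, synaptic normalization and intrinsic
    (firing-threshold) plasticity. Implements the four-phase stimulation
    paradigm (warm-up, training, relaxation, recall testing), extraction of
    post-cue spiking responses, per-neuron stimulus tuning and mutual
    information, stimulus decoding from random readout subsets (perceptron,
    linear SVM, k-nearest neighbours), analyses of the emerging synaptic
    weight structure, and the analytic models for decoding probability,
    readout coverage and metabolic wiring cost. A synthetic tuned-Bernoulli
    response generator makes every analysis stage testable without running
    the full simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    e1071,
    class
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
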