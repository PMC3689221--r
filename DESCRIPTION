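Package: episodenet
Title: Recurrent Spiking Networks that Learn Noisy Spike-Pattern Episodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of recurrent spiking neural networks that
    learn spatiotemporal spike-pattern episodes from noisy, incomplete
    presentations. Provides conductance-based Izhikevich neuron dynamics with
    homeostatic scaling of excitatory input, triplet spike-timing-dependent
    plasticity (STDP) for excitatory synapses and symmetric top-hat STDP for
    inhibitory synapses, three network variants (simple, alternate, preplay),
    a theta/gamma-modulated episode stimulus generator with per-presentation
    dropout and Poisson noise, a fast compiled simulation engine with a scalar
    reference implementation, and analysis tools for prospective firing,
    pattern completion, replay/preplay order scoring and weight-trajectory
    geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
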