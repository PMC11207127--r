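Package: tcsleep
Title: Thalamocortical Network Simulation of Sleep Spindles and Slow
    Oscillations with Closed-Loop Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conductance-based (Hodgkin-Huxley) simulation of a
    four-layer thalamocortical network that generates the two hallmark
    rhythms of NREM sleep: cortical slow oscillations (alternating silent
    Down states and depolarized Up states in coupled pyramidal and
    interneuron layers) and thalamic sleep spindles (10-16 Hz bursts from
    the reciprocal thalamocortical/reticular loop, paced by the T-type
    calcium current and the calcium-regulated h-current).  Includes an
    online slow-oscillation detector, a sensory-neuron stimulation pathway
    and closed-loop protocols (double-cue CLS, single-cue sCLS, and
    driving stimulation DSt) that deliver 20 ms cues at configurable
    slow-oscillation phases, plus an analysis layer for the cortical local
    field potential: Welch power spectra, spectrograms, sigma-band spindle
    detection, event densities and inter-spindle intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
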