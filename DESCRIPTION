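Package: pttquant
Title: Absolute Quantification of Premature Transcription Termination by RNase H Cleavage and Droplet Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying premature transcription
    termination (PTT) events, for example at bacterial riboswitches, from
    droplet digital PCR (ddPCR) readouts of RNase H-cleaved transcripts.
    Converts droplet counts into absolute template concentrations with
    Poisson statistics and confidence intervals, computes terminated and
    full-length transcript concentrations, PTT ratios, RNase H cleavage
    efficiencies and riboswitch induction ratios (IR and IR*), provides an
    RT-qPCR comparison arm (delta-delta-Ct relative quantification and
    primer-efficiency QC), and ships a simulator of the reverse
    transcription / cleavage / droplet workflow that reproduces the
    3'-distance cDNA coverage bias of random-hexamer priming.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
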