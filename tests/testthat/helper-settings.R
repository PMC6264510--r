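# the reproduction blocks can each contribute a failure when the study's
# supplementary data are not present; never stop the run early over them
options(testthat.progress.max_fails = 1000)
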