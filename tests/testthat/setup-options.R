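# Never let early failures truncate the run: every file must execute.
options(testthat.progress.max_fails = 1000L)
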