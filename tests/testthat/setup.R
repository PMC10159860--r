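# keep structured stage logging out of test output
withr::local_options(gutlink.verbose = FALSE, .local_envir = teardown_env())
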