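# Run every file to completion: a handful of expectations intentionally
# document known disagreements with the published values (see the package
# notes), and they must not cut the remaining suite short.
options(testthat.progress.max_fails = Inf)
Sys.setenv(TESTTHAT_MAX_FAILS = 1e6)
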