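#!/usr/bin/env Rscript
# Thin CLI wrapper over the qsmdgm package; see ?qsmdgm::qsm_cli
suppressPackageStartupMessages(library(qsmdgm))
status <- qsm_cli(commandArgs(trailingOnly = TRUE))
quit(status = if (is.null(status)) 0L else status)
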