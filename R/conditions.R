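# Classed conditions so callers can distinguish configuration mistakes from
# degenerate data or design problems.
abort_cellmixde <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cellmixde_error")))
}

config_error <- function(msg) abort_cellmixde(msg, "cellmixde_config_error")
param_error <- function(msg) abort_cellmixde(msg, "cellmixde_param_error")
design_error <- function(msg) abort_cellmixde(msg, "cellmixde_design_error")
degenerate_error <- function(msg) abort_cellmixde(msg, "cellmixde_degenerate_error")
alignment_error <- function(msg) abort_cellmixde(msg, "cellmixde_alignment_error")
format_error <- function(msg) abort_cellmixde(msg, "cellmixde_format_error")
convergence_error <- function(msg) abort_cellmixde(msg, "cellmixde_convergence_error")
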