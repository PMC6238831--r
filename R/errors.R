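# Classed conditions so callers (and the CLI) can react to specific
# failure modes.  Every error inherits from "um_error".

um_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "um_error")))
}

#' Machine-readable exit codes for pipeline failure modes
#'
#' Maps condition classes raised by the package to the distinct nonzero
#' process exit codes used by the command-line interface.
#'
#' @return Named integer vector: condition class -> exit code.
#' @export
um_exit_codes <- function() {
  c(um_no_sticker            = 10L,
    um_ambiguous_sticker     = 11L,
    um_no_foot               = 12L,
    um_overlapping_scribbles = 13L,
    um_out_of_bounds         = 14L,
    um_missing_marker        = 15L,
    um_empty_mask            = 16L,
    um_multiple_components   = 17L,
    um_containment_violation = 18L,
    um_no_assessment_point   = 19L,
    um_zero_baseline         = 20L,
    um_invalid_geometry      = 21L,
    um_error                 = 1L)
}
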