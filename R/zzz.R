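#' pimod: Process-Interaction Models
#'
#' One model basis, two formalisms: a Process-Interaction-Model (PIM)
#' compactly specifies a rule-based model of a signaling system and at the
#' same time determines a site-specific three-valued logical model.  See
#' \code{vignette("pimod-methods")} for the underlying concepts and
#' conventions.
#'
#' @keywords internal
"_PACKAGE"
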