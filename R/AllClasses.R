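#' @import methods
NULL

VALID_PROCESS_TYPES <- c("binding", "modification", "homodimerization", "degradation")
VALID_INFLUENCE_KINDS <- c("plain", "all_or_none")
IDENT_RE <- "^[A-Za-z][A-Za-z0-9_]*$"

#' ParameterTable: context-dependent kinetics of one process node
#'
#' One row per admissible reaction context of a process node.  The context
#' is a bit string over the node's preceding processes in ascending-id order
#' (for homodimerization nodes the predecessor bits are duplicated, one group
#' per monomer).  Rows carry the forward rate constant \code{kfw}, the
#' backward rate constant \code{kbw} (\code{NA} for irreversible processes)
#' and an optional logical override \code{y} in \code{{"0","1","*"}} used for
#' rows that have no kinetics (mutual-exclusion rows, which cannot occur in
#' the rule-based view but can in the logical view).
#'
#' @slot node integer id of the process node the table belongs to.
#' @slot inputs integer vector of preceding process ids, ascending.
#' @slot inputKinds character vector parallel to \code{inputs}, each
#'   \code{"plain"} or \code{"all_or_none"}.
#' @slot homodimer logical; \code{TRUE} when the owning node is a
#'   homodimerization process (duplicated input columns).
#' @slot rows data.frame with columns \code{ctx} (character bit string),
#'   \code{kfw}, \code{kbw} (numeric, \code{NA} allowed) and \code{y}
#'   (character, \code{NA} when no override).
#' @exportClass ParameterTable
setClass("ParameterTable",
  representation(
    node = "integer",
    inputs = "integer",
    inputKinds = "character",
    homodimer = "logical",
    rows = "data.frame"
  )
)

setValidity("ParameterTable", function(object) {
  msgs <- character(0)
  if (length(object@node) != 1L) msgs <- c(msgs, "'node' must be a single id")
  if (length(object@inputs) != length(object@inputKinds))
    msgs <- c(msgs, "'inputs' and 'inputKinds' lengths differ")
  need <- c("ctx", "kfw", "kbw", "y")
  if (!all(need %in% names(object@rows)))
    msgs <- c(msgs, sprintf("rows must have columns %s", paste(need, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' PIM: a Process-Interaction-Model
#'
#' Central container of the package.  A PIM is a directed graph whose nodes
#' are signaling processes (binding, modification, homodimerization,
#' degradation) and whose edges ("influences") state that the target process
#' occurs with context-dependent kinetics depending on whether the source
#' process has occurred.  Each node owns a \linkS4class{ParameterTable}.
#' Two thresholds \code{t1 < t2} discretize equilibrium constants into the
#' three-valued logical output used for the site-specific logical model.
#'
#' Structural soundness beyond basic slot shape is checked by
#' \code{\link{validatePim}}, which returns a report rather than failing, so
#' that broken documents can be diagnosed.
#'
#' @slot molecules named list; each element a character vector of site names
#'   of one molecule, ordered.
#' @slot processes data.frame with columns \code{id}, \code{type},
#'   \code{mol1}, \code{site1}, \code{mol2}, \code{site2}, \code{reversible}.
#'   Binding rows use both (mol, site) pairs; modification and
#'   homodimerization rows use \code{mol1}/\code{site1} only; degradation
#'   rows use \code{mol1} only.
#' @slot influences data.frame with columns \code{source}, \code{target},
#'   \code{kind} (\code{"plain"} or \code{"all_or_none"}).
#' @slot tables named list of \linkS4class{ParameterTable}, names = node ids.
#' @slot thresholds list with elements \code{t1}, \code{t2} and
#'   \code{overrides} (named list node id -> list(t1, t2)).
#' @exportClass PIM
setClass("PIM",
  representation(
    molecules = "list",
    processes = "data.frame",
    influences = "data.frame",
    tables = "list",
    thresholds = "list"
  )
)

setValidity("PIM", function(object) {
  msgs <- character(0)
  pneed <- c("id", "type", "mol1", "site1", "mol2", "site2", "reversible")
  if (!all(pneed %in% names(object@processes)))
    msgs <- c(msgs, "processes data.frame lacks required columns")
  ineed <- c("source", "target", "kind")
  if (!all(ineed %in% names(object@influences)))
    msgs <- c(msgs, "influences data.frame lacks required columns")
  if (!all(c("t1", "t2") %in% names(object@thresholds)))
    msgs <- c(msgs, "thresholds must contain t1 and t2")
  if (length(msgs)) msgs else TRUE
})

#' TruthTable: three-valued logical view of a parameter table
#'
#' Produced by \code{\link{truthTable}}.  Rows map every context bit string
#' over the node's predecessors (all-or-none predecessors included; for
#' homodimerization nodes only the equal-monomer contexts, collapsed to one
#' bit group) to an output in \code{{"0","1","*"}}.
#'
#' @slot node integer process id.
#' @slot inputs integer vector of predecessor ids, ascending.
#' @slot rows data.frame with columns \code{ctx} and \code{y}.
#' @exportClass TruthTable
setClass("TruthTable",
  representation(node = "integer", inputs = "integer", rows = "data.frame")
)

setValidity("TruthTable", function(object) {
  msgs <- character(0)
  if (!all(c("ctx", "y") %in% names(object@rows)))
    msgs <- c(msgs, "rows must have columns ctx and y")
  else if (!all(object@rows$y %in% c("0", "1", "*")))
    msgs <- c(msgs, "outputs must be 0, 1 or *")
  if (length(msgs)) msgs else TRUE
})

#' InteractionGraph: L-nodes and typed edges of the logical model
#'
#' Derived from a PIM by \code{\link{deriveInteractionGraph}}.  L-nodes are
#' molecule sites (\code{"mol.site"}), per-molecule basal activities
#' (\code{"mol"}), auxiliary nodes inserted to keep the P-node/L-node
#' correspondence one-to-one, and degradation nodes.  Edge types:
#' \code{activating} (basal to own sites, and between corresponds-to linked
#' site pairs), \code{unsigned} (one per PIM influence; sign fixed only by
#' the gate function) and \code{inhibiting} (degradation onto basal,
#' delay-flagged).
#'
#' @slot nodes data.frame with columns \code{id}, \code{role} (one of
#'   \code{site}, \code{basal}, \code{auxiliary}, \code{degradation}) and
#'   \code{molecule}.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{type},
#'   \code{delay} (logical).
#' @slot correspondsTo data.frame mapping process id (\code{pnode}) to
#'   L-node id (\code{lnode}); one row per process, no shared L-nodes.
#' @slot lcorresponds data.frame with columns \code{from}, \code{to}: the
#'   L-node-to-L-node correspondence of binding processes without prior
#'   modification.
#' @exportClass InteractionGraph
setClass("InteractionGraph",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    correspondsTo = "data.frame",
    lcorresponds = "data.frame"
  )
)

setValidity("InteractionGraph", function(object) {
  msgs <- character(0)
  if (!all(c("id", "role", "molecule") %in% names(object@nodes)))
    msgs <- c(msgs, "nodes must have id, role, molecule")
  if (!all(c("from", "to", "type", "delay") %in% names(object@edges)))
    msgs <- c(msgs, "edges must have from, to, type, delay")
  if (nrow(object@correspondsTo) &&
      anyDuplicated(object@correspondsTo$lnode))
    msgs <- c(msgs, "two P-nodes mapped to one L-node")
  if (length(msgs)) msgs else TRUE
})

#' LogicalModel: interaction graph plus DNF gate functions
#'
#' One gate per L-node.  A gate is a list with elements \code{act}
#' (character vector of activating input ids, conjoined by AND into every
#' term), \code{terms} (list of character vectors of literals over unsigned
#' inputs, \code{"!"} prefix for negation; \code{list()} is constant 0, a
#' single empty vector is constant 1), \code{itt} (logical; gate derived
#' from a truth table containing \code{*}, minimized with those rows as
#' don't-cares) and \code{delayed} (ids of delay-flagged inputs excluded
#' from steady-state evaluation).
#'
#' @slot graph the \linkS4class{InteractionGraph}.
#' @slot gates named list of gates, names = L-node ids.
#' @slot thresholds the threshold list used to discretize (provenance).
#' @exportClass LogicalModel
setClass("LogicalModel",
  representation(graph = "InteractionGraph", gates = "list", thresholds = "list")
)

setValidity("LogicalModel", function(object) {
  ids <- object@graph@nodes$id
  if (!all(names(object@gates) %in% ids))
    "gate for unknown L-node" else TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "PIM", function(object) {
  cat(sprintf(
    "PIM: %d molecules, %d processes, %d influences\n",
    length(object@molecules), nrow(object@processes), nrow(object@influences)
  ))
  tt <- table(factor(object@processes$type, levels = VALID_PROCESS_TYPES))
  cat("  processes:", paste(sprintf("%s=%d", names(tt), tt), collapse = " "), "\n")
  cat(sprintf(
    "  thresholds: t1=%g t2=%g (%d override%s)\n",
    object@thresholds$t1, object@thresholds$t2,
    length(object@thresholds$overrides),
    if (length(object@thresholds$overrides) == 1L) "" else "s"
  ))
})

setMethod("show", "ParameterTable", function(object) {
  cat(sprintf(
    "ParameterTable for node %d (%d input%s%s): %d rows\n",
    object@node, length(object@inputs),
    if (length(object@inputs) == 1L) "" else "s",
    if (object@homodimer) ", homodimer" else "",
    nrow(object@rows)
  ))
  if (nrow(object@rows)) print(object@rows, row.names = FALSE)
})

setMethod("show", "TruthTable", function(object) {
  cat(sprintf("TruthTable for node %d over inputs (%s)\n",
              object@node, paste(object@inputs, collapse = ",")))
  print(object@rows, row.names = FALSE)
})

setMethod("show", "InteractionGraph", function(object) {
  cat(sprintf("InteractionGraph: %d L-nodes, %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
  rr <- table(object@nodes$role)
  cat("  roles:", paste(sprintf("%s=%d", names(rr), rr), collapse = " "), "\n")
})

setMethod("show", "LogicalModel", function(object) {
  cat(sprintf("LogicalModel: %d L-nodes, %d gates (%d ITT)\n",
              nrow(object@graph@nodes), length(object@gates),
              sum(vapply(object@gates, function(g) isTRUE(g$itt), logical(1)))))
})
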