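## Three-valued (Kleene) logical analysis: steady states, species
## equivalence classes, minimal intervention sets.

kleeneAnd <- function(vals) {
  if (!length(vals)) return("1")
  if (any(vals == "0")) "0" else if (all(vals == "1")) "1" else "*"
}

kleeneOr <- function(vals) {
  if (!length(vals)) return("0")
  if (any(vals == "1")) "1" else if (all(vals == "0")) "0" else "*"
}

kleeneNot <- function(v) switch(v, "0" = "1", "1" = "0", "*")

gateValue <- function(gate, state) {
  actVals <- unname(state[gate$act])
  if (is.null(gate$terms)) return(kleeneAnd(actVals))  # pure AND node
  termVals <- vapply(gate$terms, function(t) {
    litVals <- vapply(t, function(lit) {
      if (startsWith(lit, "!")) kleeneNot(state[[sub("^!", "", lit)]])
      else state[[lit]]
    }, character(1))
    kleeneAnd(litVals)
  }, character(1))
  kleeneAnd(c(actVals, kleeneOr(termVals)))
}

#' One synchronous update of a logical state
#'
#' Applies every gate once under Kleene three-valued AND/OR/NOT.  Nodes in
#' \code{fixed} and model inputs keep their value; delay-flagged
#' (degradation) edges are not part of the gates and are ignored.
#'
#' @param model a \linkS4class{LogicalModel}.
#' @param state named character vector over \code{{"0","1","*"}}, total
#'   over the model's L-nodes.
#' @param fixed character vector of node ids exempt from update.
#' @return updated state.
#' @export
evaluateState <- function(model, state, fixed = character(0)) {
  ids <- model@graph@nodes$id
  stopifnot(all(ids %in% names(state)))
  out <- state
  for (nid in ids) {
    if (nid %in% fixed) next
    g <- model@gates[[nid]]
    if (isTRUE(g$input)) next
    out[[nid]] <- gateValue(g, state)
  }
  out
}

#' Scenario constructor
#'
#' A scenario fixes input (usually basal) L-nodes for analysis.  All
#' basal nodes not mentioned default to \code{on}; nodes listed in
#' \code{undefined} are left \code{*} and are the nodes whose completions
#' \code{\link{equivalenceClasses}} enumerates.  \code{stimuli} names the
#' ligand inputs excluded from the default intervention candidate set.
#'
#' @param model a \linkS4class{LogicalModel}.
#' @param off character vector of node ids fixed to 0.
#' @param on character vector fixed to 1 (in addition to the basal
#'   default).
#' @param undefined character vector left undefined.
#' @param stimuli character vector of stimulus input ids (defaults to
#'   \code{union(off, undefined)} intersected with the basal nodes).
#' @return list with \code{fixed} (named vector) and \code{stimuli}.
#' @export
makeScenario <- function(model, off = character(0), on = character(0),
                         undefined = character(0), stimuli = NULL) {
  basal <- model@graph@nodes$id[model@graph@nodes$role == "basal"]
  fixed <- stats::setNames(rep("1", length(basal)), basal)
  fixed <- fixed[!names(fixed) %in% undefined]
  for (x in on) fixed[[x]] <- "1"
  for (x in off) fixed[[x]] <- "0"
  if (is.null(stimuli))
    stimuli <- intersect(union(off, union(on, undefined)), basal)
  list(fixed = fixed, stimuli = stimuli)
}

#' Three-valued logical steady state
#'
#' Starting from the scenario's fixings with every other node unknown
#' (\code{*}), gates are applied synchronously until a fixed point is
#' reached.  Under this initialization values only move along the
#' information order (\code{*} to 0/1), so at most one pass per node is
#' needed and termination is guaranteed; nodes on unresolved feedback
#' loops stay \code{*}.
#'
#' @param model a \linkS4class{LogicalModel}.
#' @param scenario as from \code{\link{makeScenario}}: list with a named
#'   \code{fixed} vector.
#' @param interventions character vector of node ids additionally fixed
#'   to 0 (knockouts); they override scenario fixings.
#' @return named character vector (the steady state); attribute
#'   \code{"iterations"} records the number of passes.
#' @export
steadyState <- function(model, scenario, interventions = character(0)) {
  ids <- model@graph@nodes$id
  state <- stats::setNames(rep("*", length(ids)), ids)
  fixed <- scenario$fixed
  for (nid in names(fixed)) state[[nid]] <- fixed[[nid]]
  for (nid in interventions) state[[nid]] <- "0"
  fixedIds <- union(names(fixed), interventions)
  for (it in seq_len(length(ids) + 1L)) {
    nxt <- evaluateState(model, state, fixed = fixedIds)
    if (identical(nxt, state)) break
    state <- nxt
  }
  attr(state, "iterations") <- it
  state
}

#' Species equivalence classes
#'
#' Enumerates all completions of the scenario's undefined inputs, computes
#' the steady state of each, and groups L-nodes by their value vector
#' across completions.  Nodes with a constant vector are input-independent
#' and reported separately rather than as a class.
#'
#' @param model a \linkS4class{LogicalModel}.
#' @param scenario as from \code{\link{makeScenario}}.
#' @param undefined character vector of input node ids to enumerate (at
#'   most 16).
#' @return list with \code{classes} (named list of node-id vectors; names
#'   encode the value vector across completions in enumeration order),
#'   \code{constant} (input-independent node ids), \code{completions}
#'   (data.frame of enumerated input assignments) and \code{vectors}
#'   (node x completion value matrix).
#' @export
equivalenceClasses <- function(model, scenario, undefined) {
  k <- length(undefined)
  if (k > 16L) stop("too many undefined inputs (", k, " > 16)")
  ids <- model@graph@nodes$id
  combos <- bitStrings(k)
  mat <- matrix("", nrow = length(ids), ncol = length(combos),
                dimnames = list(ids, combos))
  for (j in seq_along(combos)) {
    bits <- if (k) strsplit(combos[j], "")[[1]] else character(0)
    sc <- scenario
    for (i in seq_len(k)) sc$fixed[[undefined[i]]] <- bits[i]
    st <- steadyState(model, sc)
    mat[, j] <- unname(st[ids])
  }
  keys <- apply(mat, 1, paste, collapse = "")
  constant <- ids[vapply(seq_along(ids), function(i) {
    length(unique(mat[i, ])) == 1L
  }, logical(1))]
  varying <- setdiff(ids, constant)
  classes <- split(varying, keys[match(varying, ids)])
  completions <- as.data.frame(do.call(rbind, lapply(combos, function(cc) {
    if (!k) integer(0) else as.integer(strsplit(cc, "")[[1]])
  })))
  if (k) names(completions) <- undefined
  list(classes = classes, constant = constant,
       completions = completions, vectors = mat)
}

#' Minimal intervention sets
#'
#' Exhaustive search over knockout combinations (nodes fixed to 0, up to
#' \code{kmax} at a time) that prevent the target node from reaching the
#' undesired value: the target's steady-state value must differ from
#' \code{prevent} and be defined.  Only subset-minimal sets are returned,
#' ordered by size then lexicographically.  Default candidates are all
#' site, auxiliary and basal L-nodes except the scenario's stimulus
#' inputs; the target itself is a candidate (blocking the target site
#' directly is a legitimate intervention).
#'
#' @param model a \linkS4class{LogicalModel}.
#' @param scenario as from \code{\link{makeScenario}}.
#' @param target L-node id whose activation is to be prevented.
#' @param prevent the value to prevent (default \code{"1"}).
#' @param kmax maximal intervention-set size (<= 4).
#' @param candidates optional character vector overriding the candidate
#'   node set.
#' @return list of character vectors, each a minimal intervention set.
#' @export
minimalInterventionSets <- function(model, scenario, target, prevent = "1",
                                    kmax = 2L, candidates = NULL) {
  stopifnot(kmax >= 1L, kmax <= 4L)
  nodes <- model@graph@nodes
  if (!target %in% nodes$id) stop("unknown target node ", target)
  if (is.null(candidates)) {
    candidates <- nodes$id[nodes$role %in% c("site", "basal", "auxiliary")]
    candidates <- setdiff(candidates, scenario$stimuli)
  }
  candidates <- sort(candidates)
  blocked <- function(set) {
    v <- steadyState(model, scenario, interventions = set)[[target]]
    v != prevent && v != "*"
  }
  found <- list()
  isMinimal <- function(set) {
    !any(vapply(found, function(s) all(s %in% set), logical(1)))
  }
  for (k in seq_len(kmax)) {
    if (length(candidates) < k) break
    sets <- utils::combn(candidates, k, simplify = FALSE)
    for (s in sets) {
      if (!isMinimal(s)) next
      if (blocked(s)) found[[length(found) + 1L]] <- s
    }
  }
  ord <- order(vapply(found, length, integer(1)),
               vapply(found, paste, character(1), collapse = ","))
  found[ord]
}

#' Intervention sets as a TSV report
#'
#' @param sets list as returned by \code{\link{minimalInterventionSets}}.
#' @return character vector of TSV lines.
#' @export
misTsv <- function(sets) {
  c("size\tnodes",
    vapply(sets, function(s) sprintf("%d\t%s", length(s),
                                     paste(s, collapse = ",")), character(1)))
}
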