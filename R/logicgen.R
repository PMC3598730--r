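siteNodeId <- function(mol, site) paste(mol, site, sep = ".")

# is `p` a binding process with prior modification, i.e. gated by an
# all-or-none influence from the modification process of one of its own
# bound sites?  returns the modifying process id and which side, or NULL.
priorModification <- function(pim, p) {
  preds <- predecessorsOf(pim, p$id)
  aon <- preds$id[preds$kind == "all_or_none"]
  for (q in aon) {
    qq <- processRow(pim, q)
    if (qq$type != "modification") next
    if (qq$mol1 == p$mol1 && qq$site1 == p$site1)
      return(list(mod = q, side = 1L))
    if (!is.na(p$mol2) && qq$mol1 == p$mol2 && qq$site1 == p$site2)
      return(list(mod = q, side = 2L))
  }
  NULL
}

#' Derive L-nodes and the corresponds-to relation
#'
#' Creates one site L-node per (molecule, site) referenced by any process,
#' one basal-activity L-node per molecule (the inputs of the logical
#' model) and one L-node per degradation process, then associates every
#' P-node with exactly one L-node: a modification or homodimerization
#' process with its unique site; a binding process with prior modification
#' with the partner site (the modified site already belongs to the
#' modification process); a binding process without prior modification
#' with one of its two sites -- by default the site of the second-listed
#' molecule, the other site then corresponds to it (an L-node-to-L-node
#' link realized as an activating edge).  When two binding processes would
#' claim the same L-node (one molecule binding, via the same site, two
#' partners), an auxiliary L-node named \code{"site#processId"} is
#' inserted for the later process so the mapping stays one-to-one.
#'
#' @param pim a valid \linkS4class{PIM}.
#' @param orientation \code{"second"} (default) or \code{"first"}: which
#'   bound site corresponds to a binding process without prior
#'   modification.  The choice is arbitrary and does not affect analysis
#'   results downstream of the pair.
#' @return list with \code{nodes} (data.frame id/role/molecule),
#'   \code{correspondsTo} (data.frame pnode/lnode) and \code{lcorresponds}
#'   (data.frame from/to).
#' @export
deriveLNodes <- function(pim, orientation = c("second", "first")) {
  orientation <- match.arg(orientation)
  pr <- pim@processes[order(pim@processes$id), , drop = FALSE]

  nodes <- data.frame(id = character(0), role = character(0),
                      molecule = character(0), stringsAsFactors = FALSE)
  addNode <- function(id, role, mol) {
    if (!id %in% nodes$id)
      nodes <<- rbind(nodes, data.frame(id = id, role = role, molecule = mol,
                                        stringsAsFactors = FALSE))
  }
  for (m in names(pim@molecules)) addNode(m, "basal", m)
  for (i in seq_len(nrow(pr))) {
    p <- pr[i, ]
    if (p$type == "degradation") next
    addNode(siteNodeId(p$mol1, p$site1), "site", p$mol1)
    if (p$type == "binding") addNode(siteNodeId(p$mol2, p$site2), "site", p$mol2)
  }

  cmap <- data.frame(pnode = integer(0), lnode = character(0),
                     stringsAsFactors = FALSE)
  lcor <- data.frame(from = character(0), to = character(0),
                     stringsAsFactors = FALSE)
  taken <- character(0)
  claim <- function(pid, lnode, mol) {
    if (lnode %in% taken) {            # insert auxiliary node (shared site)
      lnode <- sprintf("%s#%d", lnode, pid)
      addNode(lnode, "auxiliary", mol)
    }
    taken <<- c(taken, lnode)
    cmap <<- rbind(cmap, data.frame(pnode = pid, lnode = lnode,
                                    stringsAsFactors = FALSE))
    lnode
  }

  for (i in seq_len(nrow(pr))) {
    p <- pr[i, ]
    if (p$type %in% c("modification", "homodimerization")) {
      claim(p$id, siteNodeId(p$mol1, p$site1), p$mol1)
    } else if (p$type == "degradation") {
      dn <- sprintf("%s.deg%d", p$mol1, p$id)
      addNode(dn, "degradation", p$mol1)
      claim(p$id, dn, p$mol1)
    } else {
      pm <- priorModification(pim, p)
      if (!is.null(pm)) {
        # modified site belongs to the modification process; partner site
        # represents the binding
        if (pm$side == 1L) claim(p$id, siteNodeId(p$mol2, p$site2), p$mol2)
        else claim(p$id, siteNodeId(p$mol1, p$site1), p$mol1)
      } else {
        modifiable <- function(mol, site) {
          any(pim@processes$type == "modification" &
                pim@processes$mol1 == mol & pim@processes$site1 == site)
        }
        m1 <- modifiable(p$mol1, p$site1)
        m2 <- modifiable(p$mol2, p$site2)
        # prefer claiming a plain site; the arbitrary orientation choice
        # only remains when both sides are alike
        side <- if (m1 != m2) {
          if (m2) 1L else 2L
        } else if (orientation == "second") 2L else 1L
        if (side == 2L) {
          ln <- claim(p$id, siteNodeId(p$mol2, p$site2), p$mol2)
          src <- if (m1) p$mol1 else siteNodeId(p$mol1, p$site1)
        } else {
          ln <- claim(p$id, siteNodeId(p$mol1, p$site1), p$mol1)
          src <- if (m2) p$mol2 else siteNodeId(p$mol2, p$site2)
        }
        # a modifiable partner site carries modification state, not mere
        # presence; the pass-through then comes from the partner's basal
        lcor <- rbind(lcor, data.frame(from = src, to = ln,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  list(nodes = nodes, correspondsTo = cmap, lcorresponds = lcor)
}

#' Derive the interaction graph of the site-specific logical model
#'
#' Edges: an activating edge from every molecule's basal L-node to each of
#' its site/auxiliary/degradation L-nodes (encoding molecule structure and
#' presence); an activating edge along every L-node-to-L-node
#' correspondence (the free partner site passes the basal value on); one
#' unsigned edge per PIM influence, oriented as in the PIM, between the
#' corresponding L-nodes; and a delay-flagged inhibiting edge from each
#' degradation L-node to the basal node of the degraded molecule.
#'
#' @inheritParams deriveLNodes
#' @return an \linkS4class{InteractionGraph}.
#' @export
deriveInteractionGraph <- function(pim, orientation = c("second", "first")) {
  orientation <- match.arg(orientation)
  ln <- deriveLNodes(pim, orientation)
  edges <- data.frame(from = character(0), to = character(0),
                      type = character(0), delay = logical(0),
                      stringsAsFactors = FALSE)
  addEdge <- function(from, to, type, delay = FALSE) {
    edges <<- rbind(edges, data.frame(from = from, to = to, type = type,
                                      delay = delay, stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(ln$nodes))) {
    nd <- ln$nodes[i, ]
    if (nd$role %in% c("site", "auxiliary", "degradation"))
      addEdge(nd$molecule, nd$id, "activating")
  }
  for (i in seq_len(nrow(ln$lcorresponds)))
    addEdge(ln$lcorresponds$from[i], ln$lcorresponds$to[i], "activating")
  lmap <- stats::setNames(ln$correspondsTo$lnode,
                          as.character(ln$correspondsTo$pnode))
  inf <- pim@influences[order(pim@influences$source, pim@influences$target), ,
                        drop = FALSE]
  for (i in seq_len(nrow(inf)))
    addEdge(lmap[[as.character(inf$source[i])]],
            lmap[[as.character(inf$target[i])]], "unsigned")
  pr <- pim@processes
  for (i in which(pr$type == "degradation"))
    addEdge(lmap[[as.character(pr$id[i])]], pr$mol1[i], "inhibiting", delay = TRUE)

  new("InteractionGraph", nodes = ln$nodes, edges = edges,
      correspondsTo = ln$correspondsTo, lcorresponds = ln$lcorresponds)
}

#' Synthesize a DNF gate from a three-valued truth table
#'
#' Fully defined tables (\code{{0,1}} outputs only) are minimized with the
#' Quine-McCluskey algorithm.  Tables containing \code{*} are flagged as
#' incomplete-truth-table (ITT) gates and handled by policy:
#' \code{"conservative"} (default) excludes the unknown rows from both the
#' on-set and the off-set, running the minimization with them as
#' don't-cares; \code{"as0"}/\code{"as1"} force them to 0/1.  All
#' activating inputs are then conjoined by AND into every product term.
#'
#' @param tt a \linkS4class{TruthTable}.
#' @param inputNodes character vector of L-node ids, parallel to
#'   \code{tt@inputs} (the unsigned-edge sources).
#' @param activating character vector of activating input L-node ids.
#' @param ittPolicy one of \code{"conservative"}, \code{"as0"}, \code{"as1"}.
#' @return a gate: list with \code{act}, \code{terms} (list of literal
#'   vectors, \code{"!"} prefix = negated), \code{inputs}, \code{itt}.
#' @export
synthesizeGate <- function(tt, inputNodes = character(0),
                           activating = character(0),
                           ittPolicy = c("conservative", "as0", "as1")) {
  ittPolicy <- match.arg(ittPolicy)
  n <- length(tt@inputs)
  stopifnot(length(inputNodes) == n)
  ys <- tt@rows$y
  if (length(ys) && all(ys == "*"))
    stop("cannot synthesize a gate from an all-unknown truth table")
  ms <- strtoi(tt@rows$ctx, base = 2L)
  if (n == 0L) ms <- 0L
  on <- ms[ys == "1"]
  off <- ms[ys == "0"]
  dc <- ms[ys == "*"]
  if (ittPolicy == "as0") { off <- c(off, dc); dc <- integer(0) }
  if (ittPolicy == "as1") { on <- c(on, dc); dc <- integer(0) }

  terms <- list()
  if (length(on)) {
    tstr <- minimizeDnf(on, dc, n)
    terms <- lapply(tstr, function(t) {
      lits <- character(0)
      if (n > 0) {
        bits <- strsplit(t, "")[[1]]
        for (k in seq_len(n)) {
          if (bits[k] == "1") lits <- c(lits, inputNodes[k])
          else if (bits[k] == "0") lits <- c(lits, paste0("!", inputNodes[k]))
        }
      }
      lits
    })
  }
  list(act = activating, terms = terms, inputs = inputNodes,
       itt = any(ys == "*"), delayed = character(0))
}

#' Derive the complete site-specific logical model
#'
#' Two steps: \code{\link{deriveInteractionGraph}}, then one gate per
#' L-node.  A node with a corresponding P-node gets the Quine-McCluskey
#' gate of that node's truth table (\code{\link{truthTable}},
#' \code{\link{synthesizeGate}}) AND-conjoined with its activating inputs;
#' a node with only activating inputs gets the plain AND of those inputs;
#' a node without inputs is a model input (basal activities).  In the rare
#' case of several gates feeding one node they are combined by OR.
#' Delay-flagged (degradation) in-edges are recorded on the gate but
#' excluded from steady-state evaluation.
#'
#' @inheritParams deriveLNodes
#' @param ittPolicy forwarded to \code{\link{synthesizeGate}}.
#' @return a \linkS4class{LogicalModel}.
#' @export
deriveLogicalModel <- function(pim, orientation = c("second", "first"),
                               ittPolicy = "conservative") {
  orientation <- match.arg(orientation)
  rep <- validatePim(pim)
  if (!rep$ok) stop("invalid PIM: ", paste(rep$errors, collapse = "; "))
  g <- deriveInteractionGraph(pim, orientation)
  lmap <- stats::setNames(g@correspondsTo$lnode,
                          as.character(g@correspondsTo$pnode))
  gates <- list()
  for (i in seq_len(nrow(g@nodes))) {
    nid <- g@nodes$id[i]
    inEdges <- g@edges[g@edges$to == nid, , drop = FALSE]
    delayed <- inEdges$from[inEdges$delay]
    inEdges <- inEdges[!inEdges$delay, , drop = FALSE]  # delay edges: metadata only
    act <- inEdges$from[inEdges$type == "activating"]
    pids <- g@correspondsTo$pnode[g@correspondsTo$lnode == nid]
    if (length(pids)) {
      partGates <- lapply(pids, function(pid) {
        tt <- truthTable(pim, pid)
        synthesizeGate(tt, inputNodes = unname(lmap[as.character(tt@inputs)]),
                       activating = act, ittPolicy = ittPolicy)
      })
      gate <- partGates[[1]]
      if (length(partGates) > 1L) {   # alternative routes combine by OR
        for (other in partGates[-1]) {
          gate$terms <- c(gate$terms, other$terms)
          gate$itt <- gate$itt || other$itt
          gate$inputs <- union(gate$inputs, other$inputs)
        }
      }
    } else if (length(act) || nrow(inEdges)) {
      gate <- list(act = act, terms = list(character(0)),
                   inputs = character(0), itt = FALSE, delayed = character(0))
    } else {
      gate <- list(act = character(0), terms = NULL, inputs = character(0),
                   itt = FALSE, input = TRUE, delayed = character(0))
    }
    gate$delayed <- delayed
    gates[[nid]] <- gate
  }
  new("LogicalModel", graph = g, gates = gates, thresholds = pim@thresholds)
}

#' Dependencies realized in the gate functions
#'
#' The influence structure actually expressed by the logical model: one
#' entry per activating input and per gate literal.  An unsigned
#' interaction-graph edge whose source does not appear in the target's
#' minimized gate (because the discretized table does not depend on it)
#' is absent here.
#'
#' @param model a \linkS4class{LogicalModel}.
#' @return data.frame with columns \code{from}, \code{to}, \code{sign}
#'   (+1 activating/positive literal, -1 negative literal).
#' @export
gateDependencies <- function(model) {
  out <- data.frame(from = character(0), to = character(0), sign = integer(0),
                    stringsAsFactors = FALSE)
  for (nid in names(model@gates)) {
    g <- model@gates[[nid]]
    if (isTRUE(g$input)) next
    for (a in g$act)
      out <- rbind(out, data.frame(from = a, to = nid, sign = 1L,
                                   stringsAsFactors = FALSE))
    seen <- character(0)
    for (t in g$terms) for (lit in t) {
      neg <- startsWith(lit, "!")
      v <- sub("^!", "", lit)
      key <- paste(v, neg)
      if (key %in% seen) next
      seen <- c(seen, key)
      out <- rbind(out, data.frame(from = v, to = nid,
                                   sign = if (neg) -1L else 1L,
                                   stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

#' Export the logical model (SIF + gates table)
#'
#' The SIF edge list has one line per interaction-graph edge,
#' \code{source<TAB>sign<TAB>target}: 1 for activating edges, -1 for
#' inhibiting (degradation) edges; an unsigned edge takes the sign of its
#' literal in the minimized gate (0 when the gate does not depend on it).
#' The gates table lists every DNF product term (activating inputs
#' included in each term) with its term index; model inputs are marked
#' \code{INPUT}.  Both outputs are deterministic.
#'
#' @param model a \linkS4class{LogicalModel}.
#' @param dir optional output directory; writes \code{model.sif},
#'   \code{gates.tsv} and \code{model.dot}.
#' @return list with character vectors \code{sif}, \code{gates},
#'   \code{dot}; invisibly when \code{dir} is given.
#' @export
exportLogic <- function(model, dir = NULL) {
  deps <- gateDependencies(model)
  e <- model@graph@edges
  sif <- character(0)
  for (i in seq_len(nrow(e))) {
    sign <- if (e$type[i] == "activating") 1L
      else if (e$type[i] == "inhibiting") -1L
      else {
        d <- deps[deps$from == e$from[i] & deps$to == e$to[i], , drop = FALSE]
        if (!nrow(d)) 0L else d$sign[1]
      }
    sif <- c(sif, sprintf("%s\t%d\t%s", e$from[i], sign, e$to[i]))
  }

  gates <- "node\tterm\tliterals\titt"
  for (nid in names(model@gates)) {
    g <- model@gates[[nid]]
    if (isTRUE(g$input)) {
      gates <- c(gates, sprintf("%s\t0\tINPUT\tFALSE", nid))
      next
    }
    if (!length(g$terms)) {
      gates <- c(gates, sprintf("%s\t0\tFALSE\t%s", nid, g$itt))
      next
    }
    for (k in seq_along(g$terms)) {
      lits <- c(g$act, g$terms[[k]])
      gates <- c(gates, sprintf("%s\t%d\t%s\t%s", nid, k,
                                if (length(lits)) paste(lits, collapse = ",") else "TRUE",
                                g$itt))
    }
  }

  dot <- c("digraph logicalModel {", "  rankdir=LR;")
  for (i in seq_len(nrow(model@graph@nodes))) {
    nd <- model@graph@nodes[i, ]
    shape <- switch(nd$role, basal = "hexagon", site = "box",
                    auxiliary = "box", degradation = "octagon", "ellipse")
    dot <- c(dot, sprintf('  "%s" [shape=%s];', nd$id, shape))
  }
  for (i in seq_len(nrow(e))) {
    style <- switch(e$type[i], activating = "solid",
                    unsigned = "dotted", inhibiting = "dashed")
    arrow <- if (e$type[i] == "inhibiting") "tee" else "normal"
    dot <- c(dot, sprintf('  "%s" -> "%s" [style=%s, arrowhead=%s];',
                          e$from[i], e$to[i], style, arrow))
  }
  dot <- c(dot, "}")

  out <- list(sif = sif, gates = gates, dot = dot)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(sif, file.path(dir, "model.sif"))
    writeLines(gates, file.path(dir, "gates.tsv"))
    writeLines(dot, file.path(dir, "model.dot"))
    return(invisible(out))
  }
  out
}
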