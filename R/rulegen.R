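## Rule generation: one BNGL reaction rule per admissible context of every
## process node.  Patterns follow "don't care, don't write": only the
## reaction-center sites and the context sites fixed by predecessor
## occurrence are written.

newInstance <- function(mol) list(mol = mol, sites = list())

setSiteState <- function(pat, idx, site, state) {
  s <- pat$inst[[idx]]$sites[[site]]
  if (is.null(s)) s <- list(state = NULL, bond = NULL)
  s$state <- state
  pat$inst[[idx]]$sites[[site]] <- s
  pat
}

setSiteBond <- function(pat, idx, site, bond) {
  s <- pat$inst[[idx]]$sites[[site]]
  if (is.null(s)) s <- list(state = NULL, bond = NULL)
  if (!is.null(s$bond) && !identical(s$bond, "open") && !identical(bond, "open"))
    stop("conflicting bonds on ", pat$inst[[idx]]$mol, ".", site)
  if (is.null(s$bond) || identical(s$bond, "open")) s$bond <- bond
  pat$inst[[idx]]$sites[[site]] <- s
  pat
}

findInstance <- function(pat, mol, scope) {
  for (idx in scope) if (pat$inst[[idx]]$mol == mol) return(idx)
  NA_integer_
}

# apply one predecessor's occurrence bit to the context pattern;
# `reserved` lists (instance, site) pairs held by the reaction center
applyPred <- function(pim, pat, pred, v, scope, reserved = list()) {
  isReserved <- function(idx, site) {
    any(vapply(reserved, function(r) r[[1]] == idx && r[[2]] == site,
               logical(1)))
  }
  q <- processRow(pim, pred)
  if (q$type == "modification") {
    idx <- findInstance(pat, q$mol1, scope)
    if (is.na(idx))
      stop("influence of process ", q$id,
           " not expressible: molecule ", q$mol1, " not in the rule pattern")
    pat <- setSiteState(pat, idx, q$site1, if (v) "M" else "U")
  } else if (q$type == "binding") {
    # instances of each bound molecule whose binding site is still free;
    # an instance bonded by another predecessor is a different molecule copy
    freeInst <- function(mol, site) {
      for (idx in scope) {
        if (pat$inst[[idx]]$mol != mol) next
        if (isReserved(idx, site)) next
        s <- pat$inst[[idx]]$sites[[site]]
        if (is.null(s) || is.null(s$bond) || identical(s$bond, "open"))
          return(idx)
      }
      NA_integer_
    }
    f1 <- freeInst(q$mol1, q$site1)
    f2 <- freeInst(q$mol2, q$site2)
    if (v) {
      if (!is.na(f1) && !is.na(f2) && f1 != f2) {
        pat$bond <- pat$bond + 1L
        pat <- setSiteBond(pat, f1, q$site1, pat$bond)
        pat <- setSiteBond(pat, f2, q$site2, pat$bond)
      } else if (!is.na(f1) || !is.na(f2)) {
        if (!is.na(f1)) {
          idx <- f1; aSite <- q$site1; pMol <- q$mol2; pSite <- q$site2
        } else {
          idx <- f2; aSite <- q$site2; pMol <- q$mol1; pSite <- q$site1
        }
        pat$bond <- pat$bond + 1L
        pat <- setSiteBond(pat, idx, aSite, pat$bond)
        pat$inst[[length(pat$inst) + 1L]] <- newInstance(pMol)
        pat <- setSiteBond(pat, length(pat$inst), pSite, pat$bond)
        pat$scopeAdd <- c(pat$scopeAdd, length(pat$inst))
      } else {
        stop("influence of process ", q$id,
             " not expressible: no free binding site in the rule pattern")
      }
    } else {
      anyInst <- !is.na(findInstance(pat, q$mol1, scope)) ||
        !is.na(findInstance(pat, q$mol2, scope))
      if (!anyInst)
        stop("influence of process ", q$id,
             " not expressible: neither bound molecule in the rule pattern")
      # a site already bonded to a different partner implies non-occurrence;
      # only free sites need the explicit unbound marker
      if (!is.na(f1)) pat <- setSiteBond(pat, f1, q$site1, "open")
      if (!is.na(f2) && !identical(f1, f2)) pat <- setSiteBond(pat, f2, q$site2, "open")
    }
  } else if (q$type == "homodimerization") {
    idx <- NA_integer_
    for (i2 in scope) {
      if (pat$inst[[i2]]$mol != q$mol1 || isReserved(i2, q$site1)) next
      s <- pat$inst[[i2]]$sites[[q$site1]]
      if (is.null(s) || is.null(s$bond) || identical(s$bond, "open")) {
        idx <- i2; break
      }
    }
    if (is.na(idx)) {
      if (!is.na(findInstance(pat, q$mol1, scope)) && !v)
        return(pat)  # dimerization impossible here; non-occurrence implicit
      stop("influence of process ", q$id,
           " not expressible: molecule ", q$mol1,
           " has no free dimerization site in the rule pattern")
    }
    if (v) {
      pat$bond <- pat$bond + 1L
      pat <- setSiteBond(pat, idx, q$site1, pat$bond)
      pat$inst[[length(pat$inst) + 1L]] <- newInstance(q$mol1)
      pat <- setSiteBond(pat, length(pat$inst), q$site1, pat$bond)
      pat$scopeAdd <- c(pat$scopeAdd, length(pat$inst))
    } else {
      pat <- setSiteBond(pat, idx, q$site1, "open")
    }
  } else {
    stop("degradation processes cannot precede other processes")
  }
  pat
}

renderSide <- function(pim, pat, center, side) {
  ## effective per-site (state, bond) for this side
  eff <- lapply(seq_along(pat$inst), function(idx) {
    inst <- pat$inst[[idx]]
    sites <- inst$sites
    if (center$type == "modification" && idx == center$i1 &&
        !is.null(center$site1)) {
      s <- sites[[center$site1]]
      if (is.null(s)) s <- list(state = NULL, bond = NULL)
      s$state <- if (side == "lhs") "U" else "M"
      sites[[center$site1]] <- s
    }
    if (center$type %in% c("binding", "homodimerization")) {
      for (k in 1:2) {
        ci <- if (k == 1) center$i1 else center$i2
        cs <- if (k == 1) center$site1 else center$site2
        if (idx == ci) {
          s <- sites[[cs]]
          if (is.null(s)) s <- list(state = NULL, bond = NULL)
          s$bond <- if (side == "lhs") "open" else 1L
          sites[[cs]] <- s
        }
      }
    }
    sites
  })

  instStr <- vapply(seq_along(pat$inst), function(idx) {
    inst <- pat$inst[[idx]]
    order <- pim@molecules[[inst$mol]]
    parts <- character(0)
    for (site in order) {
      s <- eff[[idx]][[site]]
      if (is.null(s)) next
      str <- site
      if (!is.null(s$state)) str <- paste0(str, "~", s$state)
      if (!is.null(s$bond) && !identical(s$bond, "open"))
        str <- paste0(str, "!", s$bond)
      parts <- c(parts, str)
    }
    paste0(inst$mol, "(", paste(parts, collapse = ","), ")")
  }, character(1))

  ## connected components via shared numeric bond labels
  comp <- seq_along(pat$inst)
  labels <- list()
  for (idx in seq_along(pat$inst)) {
    for (s in eff[[idx]]) {
      if (!is.null(s$bond) && !identical(s$bond, "open"))
        labels[[as.character(s$bond)]] <- c(labels[[as.character(s$bond)]], idx)
    }
  }
  for (members in labels) {
    tgt <- min(comp[members])
    comp[comp %in% comp[members]] <- tgt
  }
  complexes <- character(0)
  for (c0 in unique(comp)) {
    members <- which(comp == c0)
    complexes <- c(complexes, paste(instStr[members], collapse = "."))
  }
  paste(complexes, collapse = " + ")
}

ruleForContext <- function(pim, node, ctx) {
  p <- processRow(pim, node)
  preds <- predecessorsOf(pim, node)
  pat <- list(inst = list(), bond = 1L, scopeAdd = integer(0))

  if (p$type == "binding") {
    pat$inst <- list(newInstance(p$mol1), newInstance(p$mol2))
    center <- list(type = "binding", i1 = 1L, i2 = 2L,
                   site1 = p$site1, site2 = p$site2)
    groups <- list(list(bits = ctx, scope = c(1L, 2L)))
  } else if (p$type == "modification") {
    pat$inst <- list(newInstance(p$mol1))
    center <- list(type = "modification", i1 = 1L, site1 = p$site1)
    groups <- list(list(bits = ctx, scope = 1L))
  } else if (p$type == "homodimerization") {
    pat$inst <- list(newInstance(p$mol1), newInstance(p$mol1))
    center <- list(type = "homodimerization", i1 = 1L, i2 = 2L,
                   site1 = p$site1, site2 = p$site1)
    n <- nrow(preds)
    groups <- list(list(bits = substr(ctx, 1L, n), scope = 1L),
                   list(bits = substr(ctx, n + 1L, 2L * n), scope = 2L))
  } else { # degradation
    pat$inst <- list(newInstance(p$mol1))
    center <- list(type = "degradation", i1 = 1L)
    groups <- list(list(bits = ctx, scope = 1L))
  }

  reserved <- if (p$type == "binding") {
    list(list(1L, p$site1), list(2L, p$site2))
  } else if (p$type == "homodimerization") {
    list(list(1L, p$site1), list(2L, p$site1))
  } else list()

  for (g in groups) {
    scope <- g$scope
    bits <- if (nchar(g$bits)) strsplit(g$bits, "")[[1]] else character(0)
    ord <- order(preds$id)
    # binding-like predecessors first so attachments exist before
    # modification context is placed on them
    kindRank <- ifelse(preds$kind == "all_or_none", 0L, 0L) +
      ifelse(pim@processes$type[match(preds$id, pim@processes$id)] ==
               "modification", 1L, 0L)
    ord <- ord[order(kindRank[ord], preds$id[ord])]
    for (k in ord) {
      pat$scopeAdd <- integer(0)
      pat <- applyPred(pim, pat, preds$id[k], bits[k] == "1", scope, reserved)
      scope <- c(scope, pat$scopeAdd)
    }
  }

  lhs <- renderSide(pim, pat, center, "lhs")
  rhs <- if (p$type == "degradation") "0" else renderSide(pim, pat, center, "rhs")

  tab <- pim@tables[[as.character(p$id)]]
  j <- match(ctx, tab@rows$ctx)
  if (is.na(j)) stop("no parameter row for node ", node, " context '", ctx, "'")
  kfw <- tab@rows$kfw[j]
  kbw <- tab@rows$kbw[j]
  sym <- FALSE
  if (p$type == "homodimerization") {
    n <- nrow(preds)
    sym <- substr(ctx, 1L, n) == substr(ctx, n + 1L, 2L * n)
    if (sym) kfw <- 0.5 * kfw   # identical monomers: symmetry factor
  }
  suffix <- if (nchar(ctx)) paste0("_c", ctx) else ""
  kfName <- sprintf("kf_n%d%s", p$id, suffix)
  kbName <- sprintf("kb_n%d%s", p$id, suffix)
  rev <- isTRUE(p$reversible)
  text <- if (rev) sprintf("%s <-> %s %s, %s", lhs, rhs, kfName, kbName)
          else sprintf("%s -> %s %s", lhs, rhs, kfName)
  list(node = p$id, ctx = ctx, reversible = rev, symmetric = sym,
       kfw = kfw, kbw = kbw, kfName = kfName, kbName = kbName,
       lhs = lhs, rhs = rhs, text = text)
}

#' Reaction rules of one process node
#'
#' One rule per admissible context (see \code{\link{enumerateContexts}}).
#' The reaction center comes from the node's site assignments; the context
#' is written identically on both rule sides: an occurred binding
#' predecessor shows the bond with its partner pattern attached, an
#' occurred modification predecessor shows the modified site, a
#' non-occurred predecessor shows the unbound/unmodified site.
#' Homodimerization rules whose two monomers are in the same context carry
#' half the nominal forward rate constant.
#'
#' @param pim a \linkS4class{PIM}.
#' @param node integer process id.
#' @return list of rules; each rule a list with \code{node}, \code{ctx},
#'   \code{lhs}, \code{rhs}, \code{kfw}, \code{kbw}, \code{text} and the
#'   generated parameter names.
#' @export
rulesForNode <- function(pim, node) {
  lapply(enumerateContexts(pim, node), function(ctx) ruleForContext(pim, node, ctx))
}

#' Export a PIM as a BNGL model
#'
#' Emits a complete BioNetGen model: \code{parameters} (one named rate
#' constant per node and context), \code{molecule types} (modification
#' sites with \code{~U~M} states), \code{seed species} (uncomplexed
#' molecules with all sites unmodified, concentration 1 -- adjust before
#' simulation) and \code{reaction rules} (nodes ascending, contexts in
#' enumeration order).  Output is deterministic.
#'
#' @param pim a valid \linkS4class{PIM}.
#' @param path optional file to write to.
#' @return character vector of BNGL lines, invisibly when \code{path} is
#'   given.
#' @export
exportBngl <- function(pim, path = NULL) {
  rep <- validatePim(pim)
  if (!rep$ok)
    stop("invalid PIM: ", paste(rep$errors, collapse = "; "))

  ids <- sort(pim@processes$id)
  rules <- unlist(lapply(ids, function(i) rulesForNode(pim, i)), recursive = FALSE)

  fmtNum <- function(x) format(x, scientific = FALSE, trim = TRUE)
  parLines <- character(0)
  for (r in rules) {
    parLines <- c(parLines, sprintf("  %s %s", r$kfName, fmtNum(r$kfw)))
    if (r$reversible)
      parLines <- c(parLines, sprintf("  %s %s", r$kbName, fmtNum(r$kbw)))
  }

  modCapable <- function(mol, site) {
    any(pim@processes$type == "modification" &
          pim@processes$mol1 == mol & pim@processes$site1 == site)
  }
  typeLines <- vapply(names(pim@molecules), function(m) {
    ss <- vapply(pim@molecules[[m]], function(s) {
      if (modCapable(m, s)) paste0(s, "~U~M") else s
    }, character(1))
    sprintf("  %s(%s)", m, paste(ss, collapse = ","))
  }, character(1))

  seedLines <- vapply(names(pim@molecules), function(m) {
    ss <- vapply(pim@molecules[[m]], function(s) {
      if (modCapable(m, s)) paste0(s, "~U") else s
    }, character(1))
    sprintf("  %s(%s) 1", m, paste(ss, collapse = ","))
  }, character(1))

  ruleLines <- character(0)
  for (i in ids) {
    p <- processRow(pim, i)
    desc <- if (p$type == "binding") {
      sprintf("binding %s.%s - %s.%s", p$mol1, p$site1, p$mol2, p$site2)
    } else if (p$type == "degradation") {
      sprintf("degradation of %s", p$mol1)
    } else {
      sprintf("%s %s.%s", p$type, p$mol1, p$site1)
    }
    ruleLines <- c(ruleLines, sprintf("  # process %d: %s", i, desc))
    for (r in rules[vapply(rules, function(x) x$node == i, logical(1))])
      ruleLines <- c(ruleLines, paste0("  ", r$text))
  }

  lines <- c(
    "# generated by pimod",
    "# modification site states: ~U unmodified, ~M modified",
    "# symmetric homodimerization contexts carry 0.5 x the nominal forward rate",
    "# seed species concentrations are placeholders; adjust before simulation",
    "begin model",
    "begin parameters", parLines, "end parameters",
    "begin molecule types", typeLines, "end molecule types",
    "begin seed species", seedLines, "end seed species",
    "begin reaction rules", ruleLines, "end reaction rules",
    "end model")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Count reaction rules in BNGL text
#'
#' @param lines character vector of BNGL lines (as from
#'   \code{\link{exportBngl}}).
#' @return integer number of reaction-rule lines.
#' @export
bnglRuleCount <- function(lines) {
  a <- grep("^begin reaction rules$", lines)
  b <- grep("^end reaction rules$", lines)
  if (!length(a) || !length(b)) return(0L)
  block <- lines[(a + 1L):(b - 1L)]
  block <- block[!grepl("^\\s*(#|$)", block)]
  sum(grepl("(<->|->)", block))
}

#' Remove a molecule and everything that depends on it
#'
#' Drops every process assigned to the molecule, plus (transitively) every
#' process whose all-or-none prerequisite was dropped; removes all
#' influences touching dropped processes; prunes the dropped predecessors'
#' columns from remaining tables by fixing their occurrence to 0 (rows
#' with the predecessor occurred are discarded, the column is removed).
#'
#' @param pim a \linkS4class{PIM}.
#' @param molecule molecule name.
#' @return a \linkS4class{PIM} that again passes \code{\link{validatePim}}.
#' @export
dropMolecule <- function(pim, molecule) {
  if (!molecule %in% names(pim@molecules)) stop("unknown molecule ", molecule)
  pr <- pim@processes
  dropped <- pr$id[pr$mol1 == molecule |
                     (!is.na(pr$mol2) & pr$mol2 == molecule)]
  repeat {   # cascade: AON targets of dropped processes can never occur
    aonTargets <- pim@influences$target[pim@influences$kind == "all_or_none" &
                                          pim@influences$source %in% dropped]
    new <- setdiff(aonTargets, dropped)
    if (!length(new)) break
    dropped <- c(dropped, new)
  }

  keepPr <- pr[!pr$id %in% dropped, , drop = FALSE]
  keepInf <- pim@influences[!(pim@influences$source %in% dropped |
                                pim@influences$target %in% dropped), , drop = FALSE]
  mols <- pim@molecules[names(pim@molecules) != molecule]
  th <- pim@thresholds
  th$overrides <- th$overrides[!names(th$overrides) %in% as.character(dropped)]
  skel <- Pim(mols, keepPr, keepInf, tables = list(), thresholds = th)

  tabs <- list()
  for (i in seq_len(nrow(keepPr))) {
    nodeId <- keepPr$id[i]
    old <- pim@tables[[as.character(nodeId)]]
    preds <- predecessorsOf(skel, nodeId)
    if (is.null(old)) next
    oldInputs <- old@inputs
    keepPos <- which(!oldInputs %in% dropped)
    homo <- keepPr$type[i] == "homodimerization"
    pick <- function(ctx) {
      bits <- strsplit(ctx, "")[[1]]
      n <- length(oldInputs)
      groups <- if (homo) list(bits[seq_len(n)], bits[n + seq_len(n)]) else list(bits)
      # keep rows where every dropped predecessor has occurrence 0
      for (g in groups) if (any(g[setdiff(seq_len(n), keepPos)] == "1")) return(NA_character_)
      kept <- lapply(groups, function(g) paste(g[keepPos], collapse = ""))
      if (homo && kept[[1]] > kept[[2]]) kept <- rev(kept)  # canonical pair order
      paste(unlist(kept), collapse = "")
    }
    newCtx <- vapply(old@rows$ctx, pick, character(1))
    rows <- old@rows[!is.na(newCtx), , drop = FALSE]
    rows$ctx <- newCtx[!is.na(newCtx)]
    rows <- rows[!duplicated(rows$ctx), , drop = FALSE]
    tabs[[as.character(nodeId)]] <- ParameterTable(
      node = nodeId, inputs = preds$id, inputKinds = preds$kind,
      rows = rows, homodimer = homo)
  }
  Pim(mols, keepPr, keepInf, tables = tabs, thresholds = th)
}
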