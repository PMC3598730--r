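#' Construct a PIM
#'
#' Low-level constructor used by the document reader, the shipped model
#' builders and the random generator.  Performs only shape coercion; call
#' \code{\link{validatePim}} for semantic checks.
#'
#' @param molecules named list mapping molecule name to character vector of
#'   site names.
#' @param processes data.frame with columns \code{id}, \code{type},
#'   \code{mol1}, \code{site1}, \code{mol2}, \code{site2}, \code{reversible}.
#' @param influences data.frame with columns \code{source}, \code{target},
#'   \code{kind}.
#' @param tables named list of \linkS4class{ParameterTable} (names: node ids).
#' @param thresholds list with \code{t1}, \code{t2} and optionally
#'   \code{overrides}.
#' @return a \linkS4class{PIM}.
#' @export
Pim <- function(molecules, processes, influences, tables,
                thresholds = list(t1 = 0.01, t2 = 0.1)) {
  if (is.null(influences) || !nrow(influences)) {
    influences <- data.frame(source = integer(0), target = integer(0),
                             kind = character(0), stringsAsFactors = FALSE)
  }
  processes$id <- as.integer(processes$id)
  influences$source <- as.integer(influences$source)
  influences$target <- as.integer(influences$target)
  if (is.null(thresholds$overrides)) thresholds$overrides <- list()
  new("PIM", molecules = molecules, processes = processes,
      influences = influences, tables = tables, thresholds = thresholds)
}

#' Construct a ParameterTable
#'
#' @param node integer process id.
#' @param inputs integer vector of predecessor ids (ascending).
#' @param inputKinds character vector parallel to \code{inputs}.
#' @param rows data.frame with columns \code{ctx}, \code{kfw}, \code{kbw},
#'   \code{y} (missing columns are filled with \code{NA}).
#' @param homodimer logical.
#' @return a \linkS4class{ParameterTable}.
#' @export
ParameterTable <- function(node, inputs = integer(0),
                           inputKinds = character(0), rows = NULL,
                           homodimer = FALSE) {
  if (is.null(rows)) {
    rows <- data.frame(ctx = character(0), kfw = numeric(0),
                       kbw = numeric(0), y = character(0),
                       stringsAsFactors = FALSE)
  }
  for (col in c("kfw", "kbw")) if (is.null(rows[[col]])) rows[[col]] <- NA_real_
  if (is.null(rows$y)) rows$y <- NA_character_
  rows$ctx <- as.character(rows$ctx)
  rows$kfw <- as.numeric(rows$kfw)
  rows$kbw <- as.numeric(rows$kbw)
  rows$y <- as.character(rows$y)
  new("ParameterTable", node = as.integer(node), inputs = as.integer(inputs),
      inputKinds = as.character(inputKinds), homodimer = isTRUE(homodimer),
      rows = rows[, c("ctx", "kfw", "kbw", "y")])
}

processRow <- function(pim, node) {
  i <- match(as.integer(node), pim@processes$id)
  if (is.na(i)) stop("unknown process id ", node)
  pim@processes[i, , drop = FALSE]
}

#' Preceding processes of a node
#'
#' All influence sources targeting \code{node}, in the canonical
#' ascending-id order that parameter-table columns and context bit strings
#' follow throughout the package, each tagged with its influence kind.
#'
#' @param pim a \linkS4class{PIM}.
#' @param node integer process id.
#' @return data.frame with columns \code{id} (ascending) and \code{kind}.
#' @export
predecessorsOf <- function(pim, node) {
  processRow(pim, node)  # id check
  inf <- pim@influences[pim@influences$target == as.integer(node), , drop = FALSE]
  inf <- inf[order(inf$source), , drop = FALSE]
  data.frame(id = inf$source, kind = inf$kind, stringsAsFactors = FALSE)
}

#' Mutually exclusive predecessor pairs
#'
#' Two preceding binding processes that compete for a common binding site
#' can never have occurred simultaneously in the rule-based (single
#' molecule) view, so the both-occurred context carries no kinetics.
#' Competition requires the shared (molecule, site) to lie on a
#' reaction-center molecule of \code{node}: there the site is a single
#' instance in every rule pattern and can hold only one bond.  A site
#' shared on a non-center molecule (e.g. one ligand species binding two
#' different receptor domains) is no conflict -- each occurrence attaches
#' its own copy of the ligand.  Returns every competing unordered pair.
#'
#' @param pim a \linkS4class{PIM}.
#' @param node integer process id.
#' @return data.frame with columns \code{a}, \code{b} (a < b); zero rows if
#'   none.
#' @export
mutuallyExclusiveInputs <- function(pim, node) {
  preds <- predecessorsOf(pim, node)
  out <- data.frame(a = integer(0), b = integer(0))
  if (nrow(preds) < 2L) return(out)
  self <- processRow(pim, node)
  centerMols <- stats::na.omit(c(self$mol1, self$mol2))
  pr <- pim@processes[match(preds$id, pim@processes$id), , drop = FALSE]
  bindingSites <- function(p) {
    ss <- character(0)
    if (is.na(p$type) || !p$type %in% c("binding", "homodimerization"))
      return(ss)
    if (p$mol1 %in% centerMols) ss <- c(ss, paste(p$mol1, p$site1, sep = "."))
    if (p$type == "binding" && p$mol2 %in% centerMols)
      ss <- c(ss, paste(p$mol2, p$site2, sep = "."))
    ss
  }
  sites <- lapply(seq_len(nrow(pr)), function(i) bindingSites(pr[i, ]))
  for (i in seq_len(nrow(preds) - 1L)) {
    for (j in seq(i + 1L, nrow(preds))) {
      if (length(intersect(sites[[i]], sites[[j]]))) {
        out <- rbind(out, data.frame(a = preds$id[i], b = preds$id[j]))
      }
    }
  }
  out
}

bitStrings <- function(n) {
  # all length-n bit strings in binary counting order (first position = MSB)
  if (n == 0L) return("")
  vapply(0:(2^n - 1L), function(v) {
    paste(rev(as.integer(intToBits(v))[seq_len(n)]), collapse = "")
  }, character(1))
}

monomerContexts <- function(pim, node) {
  # admissible single-monomer assignments: AON predecessors fixed at 1,
  # mutually exclusive pairs never jointly 1
  preds <- predecessorsOf(pim, node)
  n <- nrow(preds)
  ctx <- bitStrings(n)
  if (n == 0L) return(ctx)
  keep <- rep(TRUE, length(ctx))
  aon <- which(preds$kind == "all_or_none")
  me <- mutuallyExclusiveInputs(pim, node)
  for (k in seq_along(ctx)) {
    bits <- strsplit(ctx[k], "")[[1]]
    if (length(aon) && any(bits[aon] == "0")) keep[k] <- FALSE
    if (keep[k] && nrow(me)) {
      for (r in seq_len(nrow(me))) {
        ia <- match(me$a[r], preds$id); ib <- match(me$b[r], preds$id)
        if (bits[ia] == "1" && bits[ib] == "1") { keep[k] <- FALSE; break }
      }
    }
  }
  ctx[keep]
}

#' Enumerate admissible reaction contexts
#'
#' All combinations of predecessor occurrence that can appear as reaction
#' context of a rule: assignments in \code{{0,1}} over the predecessors in
#' ascending-id order, excluding (a) assignments where an all-or-none
#' predecessor has not occurred and (b) assignments where both members of a
#' mutually exclusive pair have occurred.  For homodimerization nodes each
#' context is the unordered pair of the two monomers' assignments
#' (concatenated bit groups, symmetric duplicates collapsed).  Order is
#' binary counting, so repeated calls are identical.
#'
#' @param pim a \linkS4class{PIM}.
#' @param node integer process id.
#' @return character vector of context bit strings.
#' @export
enumerateContexts <- function(pim, node) {
  p <- processRow(pim, node)
  mono <- monomerContexts(pim, node)
  if (p$type != "homodimerization") return(mono)
  out <- character(0)
  for (a in mono) for (b in mono) if (a <= b) out <- c(out, paste0(a, b))
  # binary counting order on the concatenated string
  out[order(out)]
}

#' Equilibrium constant of a context row
#'
#' \code{keq = kfw / kbw}, defined for reversible rows only.
#'
#' @param row list or one-row data.frame with elements \code{kfw} and
#'   \code{kbw}.
#' @return positive real.
#' @export
equilibriumConstant <- function(row) {
  kfw <- row$kfw
  kbw <- row$kbw
  if (is.null(kbw) || length(kbw) != 1L || is.na(kbw))
    stop("k_eq undefined for irreversible process (no backward rate)")
  if (kbw == 0) stop("k_eq undefined: backward rate constant is zero")
  kfw / kbw
}

thresholdsFor <- function(pim, node) {
  th <- pim@thresholds
  ov <- th$overrides[[as.character(node)]]
  if (!is.null(ov)) list(t1 = ov$t1, t2 = ov$t2) else list(t1 = th$t1, t2 = th$t2)
}

#' Validate a PIM
#'
#' Checks all structural invariants and returns a report instead of
#' failing, so that broken documents can be diagnosed in one pass: id
#' collisions, dangling molecule/site references, reversible degradation,
#' thresholds not strictly ordered, zero forward rates, missing or
#' duplicated context rows, kinetics on mutual-exclusion rows, bad logical
#' override values.  A site referenced by no process is a warning.
#'
#' @param pim a \linkS4class{PIM}.
#' @return list with elements \code{errors}, \code{warnings} (character
#'   vectors) and \code{ok} (\code{TRUE} iff no errors), class
#'   \code{"pimValidation"}.
#' @export
validatePim <- function(pim) {
  errs <- character(0)
  warns <- character(0)
  addErr <- function(...) errs <<- c(errs, sprintf(...))

  ## molecules
  mols <- names(pim@molecules)
  if (!length(mols)) addErr("no molecules declared")
  if (anyDuplicated(mols)) addErr("duplicate molecule names")
  for (m in mols) {
    if (!grepl(IDENT_RE, m)) addErr("molecule name '%s' is not BNGL-safe", m)
    ss <- pim@molecules[[m]]
    if (!length(ss)) addErr("molecule '%s' declares no sites", m)
    if (anyDuplicated(ss)) addErr("molecule '%s' has duplicate sites", m)
    for (s in ss) if (!grepl(IDENT_RE, s))
      addErr("site name '%s.%s' is not BNGL-safe", m, s)
  }

  ## processes
  pr <- pim@processes
  if (anyDuplicated(pr$id)) addErr("duplicate process ids")
  if (any(pr$id <= 0L | is.na(pr$id))) addErr("process ids must be positive integers")
  siteOk <- function(m, s) {
    !is.na(m) && m %in% mols && !is.na(s) && s %in% pim@molecules[[m]]
  }
  for (i in seq_len(nrow(pr))) {
    p <- pr[i, ]
    if (!p$type %in% VALID_PROCESS_TYPES) {
      addErr("process %d: unknown type '%s'", p$id, p$type)
      next
    }
    if (p$type == "binding") {
      if (!siteOk(p$mol1, p$site1) || !siteOk(p$mol2, p$site2))
        addErr("process %d: unresolved binding assignment", p$id)
      else if (p$mol1 == p$mol2 && p$site1 == p$site2)
        addErr("process %d: binding assigns the same site twice", p$id)
    } else if (p$type %in% c("modification", "homodimerization")) {
      if (!siteOk(p$mol1, p$site1))
        addErr("process %d: unresolved site assignment", p$id)
    } else { # degradation
      if (is.na(p$mol1) || !p$mol1 %in% mols)
        addErr("process %d: unresolved molecule reference", p$id)
      if (isTRUE(p$reversible))
        addErr("process %d: degradation is an irreversible process", p$id)
    }
  }

  ## influences
  inf <- pim@influences
  for (i in seq_len(nrow(inf))) {
    e <- inf[i, ]
    if (!e$source %in% pr$id || !e$target %in% pr$id)
      addErr("influence %d->%d references unknown process", e$source, e$target)
    if (!is.na(e$source) && !is.na(e$target) && e$source == e$target)
      addErr("influence %d->%d is a self-loop", e$source, e$target)
    if (!e$kind %in% VALID_INFLUENCE_KINDS)
      addErr("influence %d->%d: unknown kind '%s'", e$source, e$target, e$kind)
  }
  if (nrow(inf) && anyDuplicated(inf[, c("source", "target")]))
    addErr("more than one influence on an ordered (source,target) pair")

  ## thresholds
  checkTh <- function(t1, t2, where) {
    if (!is.numeric(t1) || !is.numeric(t2) || is.na(t1) || is.na(t2)) {
      addErr("%s: thresholds must be numeric", where)
    } else {
      if (t1 <= 0 || t2 <= 0) addErr("%s: thresholds must be positive", where)
      if (t1 >= t2) addErr("%s: thresholds not strictly ordered (t1 < t2 required)", where)
    }
  }
  checkTh(pim@thresholds$t1, pim@thresholds$t2, "global thresholds")
  for (k in names(pim@thresholds$overrides)) {
    ov <- pim@thresholds$overrides[[k]]
    checkTh(ov$t1, ov$t2, sprintf("threshold override for node %s", k))
  }

  ## tables (only for structurally sound processes)
  structuralOk <- !length(errs)
  if (structuralOk) {
    referenced <- character(0)
    for (i in seq_len(nrow(pr))) {
      p <- pr[i, ]
      referenced <- c(referenced, paste(p$mol1, p$site1, sep = "."))
      if (p$type == "binding")
        referenced <- c(referenced, paste(p$mol2, p$site2, sep = "."))
    }
    for (m in mols) for (s in pim@molecules[[m]]) {
      if (!paste(m, s, sep = ".") %in% referenced && !m %in% pr$mol1[pr$type == "degradation"])
        warns <- c(warns, sprintf("site %s.%s is referenced by no process", m, s))
    }

    # a predecessor that binds a reaction-center bond site of its target is
    # inexpressible when it has no other anchor on a center molecule: the
    # single center instance cannot hold the context bond and react at once
    centerBondSites <- function(p) {
      if (p$type == "binding")
        c(paste(p$mol1, p$site1, sep = "."), paste(p$mol2, p$site2, sep = "."))
      else if (p$type == "homodimerization") paste(p$mol1, p$site1, sep = ".")
      else character(0)
    }
    for (i in seq_len(nrow(pr))) {
      p <- pr[i, ]
      own <- centerBondSites(p)
      if (!length(own)) next
      cm <- stats::na.omit(c(p$mol1, p$mol2))
      for (qid in predecessorsOf(pim, p$id)$id) {
        q <- processRow(pim, qid)
        qs <- centerBondSites(q)
        shared <- intersect(own, qs)
        if (!length(shared)) next
        others <- setdiff(qs, own)
        otherOnCenter <- any(vapply(strsplit(others, ".", fixed = TRUE),
                                    function(x) x[1] %in% cm, logical(1)))
        if (!otherOnCenter)
          addErr("influence %d->%d competes for reaction-center site %s",
                 qid, p$id, shared[1])
      }
    }

    for (i in seq_len(nrow(pr))) {
      p <- pr[i, ]
      key <- as.character(p$id)
      if (!key %in% names(pim@tables)) {
        addErr("process %d has no parameter table", p$id)
        next
      }
      tab <- pim@tables[[key]]
      preds <- predecessorsOf(pim, p$id)
      if (!identical(as.integer(tab@inputs), as.integer(preds$id)))
        addErr("process %d: table inputs do not match predecessors", p$id)
      kinetic <- enumerateContexts(pim, p$id)
      meSet <- setdiff(fullContexts(pim, p$id), kinetic)
      rows <- tab@rows
      if (anyDuplicated(rows$ctx)) addErr("process %d: duplicate context rows", p$id)
      for (ctx in kinetic) {
        j <- match(ctx, rows$ctx)
        if (is.na(j)) {
          addErr("process %d: missing row for context '%s'", p$id, ctx)
          next
        }
        if (is.na(rows$kfw[j]))
          addErr("process %d ctx '%s': forward rate constant missing", p$id, ctx)
        else if (rows$kfw[j] <= 0)
          addErr("process %d ctx '%s': forward rate constant must be nonzero", p$id, ctx)
        if (isTRUE(p$reversible)) {
          if (is.na(rows$kbw[j]) || rows$kbw[j] <= 0)
            addErr("process %d ctx '%s': reversible row needs kbw > 0", p$id, ctx)
        } else if (!is.na(rows$kbw[j])) {
          addErr("process %d ctx '%s': irreversible table must not carry kbw", p$id, ctx)
        }
      }
      extra <- setdiff(rows$ctx, c(kinetic, meSet))
      for (ctx in extra)
        addErr("process %d: row for inadmissible context '%s'", p$id, ctx)
      for (ctx in intersect(rows$ctx, meSet)) {
        j <- match(ctx, rows$ctx)
        if (!is.na(rows$kfw[j]) || !is.na(rows$kbw[j]))
          addErr("process %d ctx '%s': mutual-exclusion row must not carry kinetics",
                 p$id, ctx)
        if (!is.na(rows$y[j]) && !rows$y[j] %in% c("0", "1", "*"))
          addErr("process %d ctx '%s': override must be 0, 1 or *", p$id, ctx)
      }
    }
    for (key in setdiff(names(pim@tables), as.character(pr$id)))
      addErr("parameter table for unknown process %s", key)
  }

  structure(list(errors = errs, warnings = warns, ok = !length(errs)),
            class = "pimValidation")
}

# all assignments with AON fixed at 1 but without the mutual-exclusion
# filter; difference to enumerateContexts() = the override-only rows
fullContexts <- function(pim, node) {
  p <- processRow(pim, node)
  preds <- predecessorsOf(pim, node)
  n <- nrow(preds)
  ctx <- bitStrings(n)
  if (n) {
    aon <- which(preds$kind == "all_or_none")
    if (length(aon)) {
      keep <- vapply(ctx, function(s) {
        all(strsplit(s, "")[[1]][aon] == "1")
      }, logical(1))
      ctx <- ctx[keep]
    }
  }
  if (p$type != "homodimerization") return(ctx)
  out <- character(0)
  for (a in ctx) for (b in ctx) if (a <= b) out <- c(out, paste0(a, b))
  out[order(out)]
}

#' @export
print.pimValidation <- function(x, ...) {
  cat(sprintf("PIM validation: %s (%d error%s, %d warning%s)\n",
              if (x$ok) "OK" else "FAILED",
              length(x$errors), if (length(x$errors) == 1L) "" else "s",
              length(x$warnings), if (length(x$warnings) == 1L) "" else "s"))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
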