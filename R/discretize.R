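#' Discretize one context row into a three-valued output
#'
#' For a reversible process the equilibrium constant \code{keq = kfw/kbw}
#' is compared against the thresholds: \code{y = 1} if \code{keq >= t2}
#' ("the process has occurred"), \code{y = 0} if \code{keq <= t1} ("has
#' not occurred"), otherwise \code{*} (unknown).  Both comparisons are
#' inclusive and exact (no epsilon).  For an irreversible process the same
#' rule is applied to the forward rate constant.  A logical override
#' \code{y} stored on the row (mutual-exclusion rows) wins unconditionally.
#'
#' @param row list or one-row data.frame with \code{kfw}, \code{kbw} and
#'   optional \code{y}.
#' @param th list with \code{t1}, \code{t2} (\code{t1 < t2}).
#' @param reversible logical.
#' @return \code{"0"}, \code{"1"} or \code{"*"}.
#' @export
discretizeRow <- function(row, th, reversible = TRUE) {
  y <- row$y
  if (!is.null(y) && length(y) == 1L && !is.na(y)) return(as.character(y))
  v <- if (reversible) equilibriumConstant(row) else row$kfw
  if (is.na(v)) stop("row without kinetics and without override")
  if (v >= th$t2) "1" else if (v <= th$t1) "0" else "*"
}

#' Three-valued truth table of a process node
#'
#' Interprets the node's parameter table as a truth table over its
#' predecessors: every kinetic row is discretized with
#' \code{\link{discretizeRow}} (per-process threshold overrides apply);
#' contexts where an all-or-none predecessor has not occurred are
#' impossible and get \code{y = 0}; mutual-exclusion contexts take the
#' row's logical override, defaulting to \code{*}.  For homodimerization
#' nodes only the equal-monomer contexts are used and the duplicated bit
#' groups collapse to one, so the table is again over single predecessor
#' occurrences.
#'
#' @param pim a \linkS4class{PIM}.
#' @param node integer process id.
#' @return a \linkS4class{TruthTable} with one row per assignment in
#'   \code{{0,1}^n}, n = number of predecessors.
#' @export
truthTable <- function(pim, node) {
  p <- processRow(pim, node)
  key <- as.character(p$id)
  if (!key %in% names(pim@tables)) stop("process ", node, " has no parameter table")
  tab <- pim@tables[[key]]
  preds <- predecessorsOf(pim, node)
  th <- thresholdsFor(pim, node)
  homo <- p$type == "homodimerization"
  aon <- which(preds$kind == "all_or_none")
  kinetic <- enumerateContexts(pim, node)
  fullSet <- fullContexts(pim, node)

  ctxAll <- bitStrings(nrow(preds))
  ys <- vapply(ctxAll, function(ctx) {
    bits <- if (nrow(preds)) strsplit(ctx, "")[[1]] else character(0)
    if (length(aon) && any(bits[aon] == "0")) return("0")
    stored <- if (homo) paste0(ctx, ctx) else ctx
    j <- match(stored, tab@rows$ctx)
    if (stored %in% kinetic) {
      discretizeRow(tab@rows[j, ], th, reversible = isTRUE(p$reversible))
    } else if (stored %in% fullSet) {
      # mutual-exclusion context: logical override or unknown
      if (!is.na(j) && !is.na(tab@rows$y[j])) tab@rows$y[j] else "*"
    } else {
      "0"
    }
  }, character(1))

  new("TruthTable", node = as.integer(node), inputs = as.integer(preds$id),
      rows = data.frame(ctx = ctxAll, y = unname(ys), stringsAsFactors = FALSE))
}

#' Truth tables for all nodes
#'
#' @param pim a \linkS4class{PIM}.
#' @return named list of \linkS4class{TruthTable}, names = node ids.
#' @export
truthTables <- function(pim) {
  ids <- sort(pim@processes$id)
  out <- lapply(ids, function(i) truthTable(pim, i))
  names(out) <- as.character(ids)
  out
}

#' Dump truth tables as TSV
#'
#' One line per (node, context) with the discretized output; used by the
#' command-line front end for inspection.
#'
#' @param pim a \linkS4class{PIM}.
#' @return character vector of TSV lines (header first).
#' @export
truthTablesTsv <- function(pim) {
  lines <- "node\tinputs\tctx\ty"
  for (tt in truthTables(pim)) {
    for (i in seq_len(nrow(tt@rows))) {
      lines <- c(lines, sprintf("%d\t%s\t%s\t%s", tt@node,
                                paste(tt@inputs, collapse = ","),
                                tt@rows$ctx[i], tt@rows$y[i]))
    }
  }
  lines
}
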