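#' Compare logical models across threshold choices
#'
#' Re-derives the site-specific logical model for each (t1, t2) pair and
#' reports the gate-level dependency edges of each model plus the pairwise
#' differences between consecutive models.  Raising both thresholds can
#' only make the model more restrictive (tables gain 0 rows, gates gain
#' dependencies); lowering can only lose them, so sweeping ordered pairs
#' exposes the nesting of model variants.
#'
#' @param pim a \linkS4class{PIM}.
#' @param pairs list of c(t1, t2) pairs, in the order to compare.
#' @param ... forwarded to \code{\link{deriveLogicalModel}}.
#' @return list with \code{models}, \code{edges} (list of data.frames from
#'   \code{\link{gateDependencies}}) and \code{diffs} (per consecutive
#'   pair: edges gained and lost, as "from->to" strings).
#' @export
sweepThresholds <- function(pim, pairs, ...) {
  models <- list()
  edges <- list()
  for (k in seq_along(pairs)) {
    p2 <- pim
    p2@thresholds$t1 <- pairs[[k]][1]
    p2@thresholds$t2 <- pairs[[k]][2]
    p2@thresholds$overrides <- list()
    key <- sprintf("t1=%g,t2=%g", pairs[[k]][1], pairs[[k]][2])
    models[[key]] <- deriveLogicalModel(p2, ...)
    edges[[key]] <- gateDependencies(models[[key]])
  }
  keyOf <- function(df) paste(df$from, df$to, sep = "->")
  diffs <- list()
  if (length(edges) > 1L) {
    for (k in seq_len(length(edges) - 1L)) {
      a <- keyOf(edges[[k]]); b <- keyOf(edges[[k + 1L]])
      diffs[[sprintf("%s vs %s", names(edges)[k], names(edges)[k + 1L])]] <-
        list(gained = sort(setdiff(b, a)), lost = sort(setdiff(a, b)))
    }
  }
  list(models = models, edges = edges, diffs = diffs)
}
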