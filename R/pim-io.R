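#' Read a PIM document
#'
#' Parses the package's YAML document format into a \linkS4class{PIM}.  Top
#' level keys: \code{molecules} (name + sites), \code{processes} (id, type,
#' sites as \code{"mol.site"} strings, or \code{molecule} for degradation,
#' reversible flag), \code{influences} (source, target, kind; kind
#' \code{bidirectional} is accepted as sugar and expanded into two plain
#' influences), \code{parameters} (per node: rows with \code{ctx} bits in
#' ascending-predecessor order, \code{kfw}, \code{kbw}, optional \code{y}
#' override for mutual-exclusion rows) and \code{thresholds} (t1, t2,
#' optional per-node \code{overrides}).
#'
#' Semantic problems beyond syntax are not raised here; run
#' \code{\link{validatePim}} on the result.
#'
#' @param text character scalar holding the document, or a list already
#'   parsed by \code{yaml}.
#' @return a \linkS4class{PIM}.
#' @seealso \code{\link{writePim}}, \code{\link{readPimFile}}
#' @export
readPim <- function(text) {
  doc <- if (is.character(text)) yaml::yaml.load(paste(text, collapse = "\n")) else text
  if (!length(doc$molecules)) stop("no molecules declared")

  mols <- list()
  for (m in doc$molecules) {
    if (is.null(m$name)) stop("molecule entry without name")
    mols[[m$name]] <- as.character(unlist(m$sites))
  }

  splitSite <- function(s) {
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("bad site reference '", s, "' (expected mol.site)")
    parts
  }
  pr <- do.call(rbind, lapply(doc$processes, function(p) {
    if (is.null(p$id) || is.null(p$type)) stop("process entry needs id and type")
    mol2 <- site2 <- NA_character_
    if (p$type == "degradation") {
      if (is.null(p$molecule)) stop("degradation process ", p$id, " needs a molecule")
      mol1 <- p$molecule; site1 <- NA_character_
      rev <- FALSE
    } else {
      ss <- as.character(unlist(p$sites))
      need <- if (p$type == "binding") 2L else 1L
      if (length(ss) != need)
        stop("process ", p$id, ": expected ", need, " site reference(s)")
      a <- splitSite(ss[1]); mol1 <- a[1]; site1 <- a[2]
      if (need == 2L) { b <- splitSite(ss[2]); mol2 <- b[1]; site2 <- b[2] }
      rev <- if (is.null(p$reversible)) TRUE else isTRUE(p$reversible)
    }
    data.frame(id = as.integer(p$id), type = p$type, mol1 = mol1, site1 = site1,
               mol2 = mol2, site2 = site2, reversible = rev,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pr)) stop("no processes declared")

  inf <- data.frame(source = integer(0), target = integer(0),
                    kind = character(0), stringsAsFactors = FALSE)
  for (e in doc$influences) {
    kind <- if (is.null(e$kind)) "plain" else e$kind
    if (kind == "bidirectional") {
      inf <- rbind(inf,
        data.frame(source = as.integer(e$source), target = as.integer(e$target),
                   kind = "plain", stringsAsFactors = FALSE),
        data.frame(source = as.integer(e$target), target = as.integer(e$source),
                   kind = "plain", stringsAsFactors = FALSE))
    } else {
      inf <- rbind(inf,
        data.frame(source = as.integer(e$source), target = as.integer(e$target),
                   kind = kind, stringsAsFactors = FALSE))
    }
  }

  th <- list(t1 = 0.01, t2 = 0.1, overrides = list())
  if (!is.null(doc$thresholds)) {
    if (!is.null(doc$thresholds$t1)) th$t1 <- as.numeric(doc$thresholds$t1)
    if (!is.null(doc$thresholds$t2)) th$t2 <- as.numeric(doc$thresholds$t2)
    for (k in names(doc$thresholds$overrides)) {
      ov <- doc$thresholds$overrides[[k]]
      th$overrides[[k]] <- list(t1 = as.numeric(ov$t1), t2 = as.numeric(ov$t2))
    }
  }

  skeleton <- Pim(mols, pr, inf, tables = list(), thresholds = th)
  tabs <- list()
  for (tb in doc$parameters) {
    nodeId <- as.integer(tb$node)
    preds <- predecessorsOf(skeleton, nodeId)
    rows <- do.call(rbind, lapply(tb$rows, function(r) {
      ctx <- paste(as.integer(unlist(r$ctx)), collapse = "")
      data.frame(ctx = ctx,
                 kfw = if (is.null(r$kfw)) NA_real_ else as.numeric(r$kfw),
                 kbw = if (is.null(r$kbw)) NA_real_ else as.numeric(r$kbw),
                 y = if (is.null(r$y)) NA_character_ else as.character(r$y),
                 stringsAsFactors = FALSE)
    }))
    isHomo <- skeleton@processes$type[match(nodeId, skeleton@processes$id)] ==
      "homodimerization"
    tabs[[as.character(nodeId)]] <- ParameterTable(
      node = nodeId, inputs = preds$id, inputKinds = preds$kind,
      rows = rows, homodimer = isTRUE(isHomo))
  }
  Pim(mols, pr, inf, tables = tabs, thresholds = th)
}

#' Write a PIM document
#'
#' Serializes to the canonical YAML form: molecules in declaration order,
#' processes and parameter blocks sorted by id, influences sorted by
#' (source, target), table rows in the deterministic context-enumeration
#' order followed by any mutual-exclusion override rows.  Identical PIMs
#' give byte-identical documents, so document equality is the package's
#' canonical PIM equality (see \code{\link{pimEqual}}).
#'
#' @param pim a \linkS4class{PIM}.
#' @return character scalar (YAML).
#' @export
writePim <- function(pim) {
  mols <- lapply(names(pim@molecules), function(m) {
    list(name = m, sites = as.list(pim@molecules[[m]]))
  })
  pr <- pim@processes[order(pim@processes$id), , drop = FALSE]
  procs <- lapply(seq_len(nrow(pr)), function(i) {
    p <- pr[i, ]
    if (p$type == "degradation") {
      list(id = p$id, type = p$type, molecule = p$mol1)
    } else {
      sites <- paste(p$mol1, p$site1, sep = ".")
      if (p$type == "binding")
        sites <- c(sites, paste(p$mol2, p$site2, sep = "."))
      list(id = p$id, type = p$type, sites = as.list(sites),
           reversible = isTRUE(p$reversible))
    }
  })
  inf <- pim@influences[order(pim@influences$source, pim@influences$target), ,
                        drop = FALSE]
  infs <- lapply(seq_len(nrow(inf)), function(i) {
    as.list(inf[i, c("source", "target", "kind")])
  })
  params <- lapply(pr$id, function(nodeId) {
    tab <- pim@tables[[as.character(nodeId)]]
    if (is.null(tab)) return(list(node = nodeId, rows = list()))
    canonical <- intersect(
      tryCatch(fullContexts(pim, nodeId), error = function(e) tab@rows$ctx),
      tab@rows$ctx)
    canonical <- c(canonical, setdiff(tab@rows$ctx, canonical))
    rows <- lapply(canonical, function(ctx) {
      j <- match(ctx, tab@rows$ctx)
      r <- list(ctx = as.list(as.integer(strsplit(ctx, "")[[1]])))
      if (!is.na(tab@rows$kfw[j])) r$kfw <- tab@rows$kfw[j]
      if (!is.na(tab@rows$kbw[j])) r$kbw <- tab@rows$kbw[j]
      if (!is.na(tab@rows$y[j])) r$y <- tab@rows$y[j]
      r
    })
    list(node = nodeId, rows = rows)
  })
  th <- list(t1 = pim@thresholds$t1, t2 = pim@thresholds$t2)
  ov <- pim@thresholds$overrides
  if (length(ov)) th$overrides <- ov[order(as.integer(names(ov)))]
  doc <- list(molecules = mols, processes = procs, influences = infs,
              parameters = params, thresholds = th)
  yaml::as.yaml(doc, precision = 15)
}

#' @rdname readPim
#' @param path file path.
#' @export
readPimFile <- function(path) {
  readPim(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' @rdname writePim
#' @param path file path.
#' @export
writePimFile <- function(pim, path) {
  writeLines(writePim(pim), path)
  invisible(path)
}

#' Canonical PIM equality
#'
#' Two PIMs are equal iff their canonical documents are byte-identical.
#'
#' @param a,b \linkS4class{PIM} objects.
#' @return logical.
#' @export
pimEqual <- function(a, b) identical(writePim(a), writePim(b))
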