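#' Random PIM generator for property testing
#'
#' Draws a structurally valid random PIM: molecules with 1-3 sites,
#' processes of all four types, plain influences restricted to pairs whose
#' context is expressible in a reaction rule (the source process must
#' involve a molecule of the target's reaction center), and all-or-none
#' influences only from a modification process onto a binding process at
#' the modified site.  Kinetic values are drawn from a fixed grid
#' straddling the default thresholds; mutual-exclusion rows occasionally
#' carry a logical override.  Deterministic for a given seed (the caller's
#' RNG state is restored).
#'
#' @param nMolecules number of molecules.
#' @param nProcesses number of process nodes.
#' @param edgeProb probability of a plain influence between an eligible
#'   ordered process pair (in-degree capped at 3, 2 for homodimerization).
#' @param seed integer seed (required).
#' @param types process types to draw from.
#' @return a \linkS4class{PIM} passing \code{\link{validatePim}}.
#' @export
randomPim <- function(nMolecules = 3L, nProcesses = 6L, edgeProb = 0.3,
                      seed, types = c("modification", "binding",
                                      "homodimerization", "degradation")) {
  if (missing(seed)) stop("seed is required for reproducibility")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)

  mols <- list()
  for (i in seq_len(nMolecules)) {
    mols[[sprintf("M%d", i)]] <- sprintf("s%d", seq_len(sample(1:3, 1)))
  }
  allSites <- do.call(rbind, lapply(names(mols), function(m) {
    data.frame(mol = m, site = mols[[m]], stringsAsFactors = FALSE)
  }))

  w <- c(modification = 0.45, binding = 0.35, homodimerization = 0.12,
         degradation = 0.08)[types]
  pr <- NULL
  for (i in seq_len(nProcesses)) {
    ty <- sample(names(w), 1, prob = w)
    if (ty == "binding" && length(mols) < 2L) ty <- "modification"
    row <- if (ty == "binding") {
      repeat {
        a <- allSites[sample(nrow(allSites), 1), ]
        b <- allSites[sample(nrow(allSites), 1), ]
        if (a$mol != b$mol) break
      }
      data.frame(id = i, type = ty, mol1 = a$mol, site1 = a$site,
                 mol2 = b$mol, site2 = b$site,
                 reversible = stats::runif(1) > 0.1, stringsAsFactors = FALSE)
    } else if (ty == "degradation") {
      data.frame(id = i, type = ty, mol1 = sample(names(mols), 1),
                 site1 = NA_character_, mol2 = NA_character_,
                 site2 = NA_character_, reversible = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      a <- allSites[sample(nrow(allSites), 1), ]
      data.frame(id = i, type = ty, mol1 = a$mol, site1 = a$site,
                 mol2 = NA_character_, site2 = NA_character_,
                 reversible = if (ty == "homodimerization") TRUE
                              else stats::runif(1) > 0.1,
                 stringsAsFactors = FALSE)
    }
    pr <- rbind(pr, row)
  }

  centerMols <- lapply(seq_len(nrow(pr)), function(i) {
    stats::na.omit(c(pr$mol1[i], pr$mol2[i]))
  })
  bondSites <- lapply(seq_len(nrow(pr)), function(i) {
    if (pr$type[i] == "binding")
      c(paste(pr$mol1[i], pr$site1[i], sep = "."),
        paste(pr$mol2[i], pr$site2[i], sep = "."))
    else if (pr$type[i] == "homodimerization")
      paste(pr$mol1[i], pr$site1[i], sep = ".")
    else character(0)
  })
  involves <- function(src, tgt) {
    length(intersect(centerMols[[src]], centerMols[[tgt]])) > 0L &&
      !length(intersect(bondSites[[src]], bondSites[[tgt]]))
  }
  inf <- data.frame(source = integer(0), target = integer(0),
                    kind = character(0), stringsAsFactors = FALSE)
  indeg <- rep(0L, nProcesses)
  cap <- ifelse(pr$type == "homodimerization", 2L, 3L)
  # all-or-none: modification process gating a binding at the modified site
  for (j in which(pr$type == "binding")) {
    for (i in which(pr$type == "modification")) {
      onSite <- (pr$mol1[i] == pr$mol1[j] && pr$site1[i] == pr$site1[j]) ||
        (pr$mol1[i] == pr$mol2[j] && pr$site1[i] == pr$site2[j])
      if (onSite && indeg[j] < cap[j] && stats::runif(1) < 0.7) {
        inf <- rbind(inf, data.frame(source = i, target = j,
                                     kind = "all_or_none",
                                     stringsAsFactors = FALSE))
        indeg[j] <- indeg[j] + 1L
      }
    }
  }
  for (i in seq_len(nProcesses)) {
    if (pr$type[i] == "degradation") next   # no context after deletion
    for (j in seq_len(nProcesses)) {
      if (i == j || !involves(i, j) || indeg[j] >= cap[j]) next
      if (nrow(inf) && any(inf$source == i & inf$target == j)) next
      if (stats::runif(1) < edgeProb) {
        inf <- rbind(inf, data.frame(source = i, target = j, kind = "plain",
                                     stringsAsFactors = FALSE))
        indeg[j] <- indeg[j] + 1L
      }
    }
  }

  skel <- Pim(mols, pr, inf, tables = list(),
              thresholds = list(t1 = 0.01, t2 = 0.1))
  grid <- c(0.005, 0.05, 0.5, 1, 5)
  specs <- list()
  for (i in seq_len(nProcesses)) {
    kin <- enumerateContexts(skel, i)
    rows <- data.frame(ctx = kin,
                       kfw = sample(grid, length(kin), replace = TRUE),
                       kbw = if (pr$reversible[i]) 1 else NA_real_,
                       y = NA_character_, stringsAsFactors = FALSE)
    # keep at least one decided context so a gate is always synthesizable
    rows$kfw[1] <- sample(setdiff(grid, 0.05), 1)
    meCtx <- setdiff(fullContexts(skel, i), kin)
    for (ctx in meCtx) {
      if (stats::runif(1) < 0.5) {
        rows <- rbind(rows, data.frame(ctx = ctx, kfw = NA_real_,
                                       kbw = NA_real_,
                                       y = sample(c("0", "1", "*"), 1),
                                       stringsAsFactors = FALSE))
      }
    }
    specs[[as.character(i)]] <- rows
  }
  fillTables(skel, specs)
}
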