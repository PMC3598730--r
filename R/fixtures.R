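procDf <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id = as.integer(r[[1]]), type = r[[2]],
               mol1 = r[[3]], site1 = if (is.na(r[[4]])) NA_character_ else r[[4]],
               mol2 = if (length(r) >= 5 && !is.na(r[[5]])) r[[5]] else NA_character_,
               site2 = if (length(r) >= 6 && !is.na(r[[6]])) r[[6]] else NA_character_,
               reversible = if (length(r) >= 7) isTRUE(r[[7]]) else TRUE,
               stringsAsFactors = FALSE)
  }))
}

infDf <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(source = as.integer(r[[1]]), target = as.integer(r[[2]]),
               kind = if (length(r) >= 3) r[[3]] else "plain",
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(source = integer(0), target = integer(0),
                      kind = character(0), stringsAsFactors = FALSE)
  out
}

# attach parameter tables to a skeleton PIM; rowSpecs: named list
# node id -> data.frame(ctx, kfw, kbw, y)
fillTables <- function(skeleton, rowSpecs) {
  tabs <- list()
  for (key in names(rowSpecs)) {
    nodeId <- as.integer(key)
    preds <- predecessorsOf(skeleton, nodeId)
    isHomo <- skeleton@processes$type[match(nodeId, skeleton@processes$id)] ==
      "homodimerization"
    tabs[[key]] <- ParameterTable(node = nodeId, inputs = preds$id,
                                  inputKinds = preds$kind,
                                  rows = rowSpecs[[key]], homodimer = isHomo)
  }
  Pim(skeleton@molecules, skeleton@processes, skeleton@influences,
      tables = tabs, thresholds = skeleton@thresholds)
}

rowsSpec <- function(ctx, kfw = NA_real_, kbw = NA_real_, y = NA_character_) {
  data.frame(ctx = as.character(ctx), kfw = kfw, kbw = kbw, y = y,
             stringsAsFactors = FALSE)
}

#' The four-process teaching example
#'
#' Three molecules: A(b1), B(b1) and a receptor-like R(b1, p1, p2).
#' Processes: 1 binding A.b1--R.b1; 2 modification of R.p1; 3 modification
#' of R.p2; 4 binding of B.b1 to the modified R.p1 (all-or-none from
#' process 2).  Influences: 1 -> 2, 2 <-> 3 and the all-or-none 2 -> 4.
#' The node-2 kinetics are chosen so that its truth table at the default
#' thresholds (t1 = 0.01, t2 = 0.1) is OR-shaped: modification of p1 is
#' negligible (keq = 0.01) unless A is bound or p2 is modified.
#'
#' @return a \linkS4class{PIM} (4 processes, 8 generated rules).
#' @export
buildSmallExample <- function() {
  mols <- list(A = "b1", B = "b1", R = c("b1", "p1", "p2"))
  pr <- procDf(
    list(1, "binding", "A", "b1", "R", "b1", TRUE),
    list(2, "modification", "R", "p1", NA, NA, TRUE),
    list(3, "modification", "R", "p2", NA, NA, TRUE),
    list(4, "binding", "B", "b1", "R", "p1", TRUE)
  )
  inf <- infDf(list(1, 2), list(2, 3), list(3, 2), list(2, 4, "all_or_none"))
  skel <- Pim(mols, pr, inf, tables = list(),
              thresholds = list(t1 = 0.01, t2 = 0.1))
  fillTables(skel, list(
    `1` = rowsSpec("", kfw = 1, kbw = 1),
    `2` = rbind(rowsSpec("00", 1, 100), rowsSpec("01", 1, 1),
                rowsSpec("10", 1, 1), rowsSpec("11", 1, 1)),
    `3` = rbind(rowsSpec("0", 1, 1), rowsSpec("1", 2, 1)),
    `4` = rowsSpec("1", kfw = 1, kbw = 1)
  ))
}

#' The 18-process EGF-insulin crosstalk model
#'
#' Early events of insulin and EGF signaling: the insulin receptor (ir)
#' with two insulin binding domains and two phosphorylation sites binding
#' Shc and IRS; the EGF receptor (egfr) with ligand binding site,
#' dimerization site and two phosphorylation sites binding Shc and Grb2;
#' Shc phosphorylation (on either receptor) recruiting Grb2, Grb2
#' recruiting Sos, and IRS phosphorylation recruiting PI3K.  Shc and Grb2
#' each use a single physical binding site for both receptors, so the
#' respective preceding binding processes are mutually exclusive.
#'
#' Graph structure: the two insulin binding processes influence each other
#' (bidirectional 1 <-> 2) and both receptor phosphorylations (edges from
#' 1 and 2 to 3 and 4); every phosphorylation-gated binding is an
#' all-or-none influence; EGF binding and receptor dimerization influence
#' each other (13 <-> 14).
#'
#' The kinetic values are synthetic: they are drawn from the small grid
#' \{0.001, 0.01, 0.1, 0.25, 1\} so that the site-specific logical models
#' derived at thresholds (0.01, 0.1), (0.001, 0.01) and (0.1, 0.25) show
#' the intended qualitative differences (mutual inhibition of the insulin
#' sites and the binding/dimerization deadlock only at the high thresholds;
#' loss of the binding dependence of Shc/IRS phosphorylation at the low
#' ones).  See the package vignette.
#'
#' @return a \linkS4class{PIM} (18 processes, 36 generated rules).
#' @export
buildEgfInsulin <- function() {
  mols <- list(
    ins = "b1",
    ir = c("b_ins", "b_ins2", "p1", "p2"),
    shc = c("b_ir", "p1"),
    grb2 = c("b_shc", "b_sos"),
    sos = "b_grb2",
    irs = c("b_ir", "p1", "p2"),
    pi3k = "b_irs",
    egf = "b1",
    egfr = c("b_egf", "d", "p1", "p2")
  )
  pr <- procDf(
    list(1, "binding", "ins", "b1", "ir", "b_ins", TRUE),
    list(2, "binding", "ins", "b1", "ir", "b_ins2", TRUE),
    list(3, "modification", "ir", "p1", NA, NA, TRUE),
    list(4, "modification", "ir", "p2", NA, NA, TRUE),
    list(5, "binding", "shc", "b_ir", "ir", "p1", TRUE),
    list(6, "modification", "shc", "p1", NA, NA, TRUE),
    list(7, "binding", "grb2", "b_shc", "shc", "p1", TRUE),
    list(8, "binding", "sos", "b_grb2", "grb2", "b_sos", TRUE),
    list(9, "binding", "irs", "b_ir", "ir", "p2", TRUE),
    list(10, "modification", "irs", "p1", NA, NA, TRUE),
    list(11, "modification", "irs", "p2", NA, NA, TRUE),
    list(12, "binding", "pi3k", "b_irs", "irs", "p2", TRUE),
    list(13, "binding", "egf", "b1", "egfr", "b_egf", TRUE),
    list(14, "homodimerization", "egfr", "d", NA, NA, TRUE),
    list(15, "modification", "egfr", "p1", NA, NA, TRUE),
    list(16, "modification", "egfr", "p2", NA, NA, TRUE),
    list(17, "binding", "shc", "b_ir", "egfr", "p1", TRUE),
    list(18, "binding", "grb2", "b_shc", "egfr", "p2", TRUE)
  )
  inf <- infDf(
    list(1, 2), list(2, 1),            # the two insulin sites influence each other
    list(1, 3), list(2, 3), list(1, 4), list(2, 4),
    list(3, 5, "all_or_none"),         # Shc binds phosphorylated ir.p1
    list(5, 6), list(17, 6),           # Shc phosphorylation needs receptor binding
    list(6, 7, "all_or_none"),         # Grb2 binds phosphorylated Shc
    list(7, 8),                        # Sos recruitment by Shc-bound Grb2
    list(4, 9, "all_or_none"),         # IRS binds phosphorylated ir.p2
    list(9, 10), list(9, 11),          # IRS phosphorylation needs receptor binding
    list(11, 12, "all_or_none"),       # PI3K binds phosphorylated irs.p2
    list(13, 14), list(14, 13),        # EGF binding <-> receptor dimerization
    list(14, 15), list(14, 16),        # receptor phosphorylation needs a dimer
    list(15, 17, "all_or_none"),       # Shc binds phosphorylated egfr.p1
    list(16, 18, "all_or_none")        # Grb2 binds phosphorylated egfr.p2
  )
  skel <- Pim(mols, pr, inf, tables = list(),
              thresholds = list(t1 = 0.01, t2 = 0.1))

  # synthetic kinetics; keq values on the grid {0.001, 0.01, 0.1, 0.25, 1}
  insSite <- rbind(rowsSpec("0", 0.25, 1),   # free partner site: strong binding
                   rowsSpec("1", 0.1, 1))    # other site occupied: weakened
  irPhos <- rbind(rowsSpec("00", 0.001, 1),  # no ligand: negligible
                  rowsSpec("01", 1, 1), rowsSpec("10", 1, 1), rowsSpec("11", 1, 1))
  fillTables(skel, list(
    `1` = insSite,
    `2` = insSite,
    `3` = irPhos,
    `4` = irPhos,
    `5` = rowsSpec("1", 1, 1),
    `6` = rbind(rowsSpec("00", 0.01, 1),     # unbound Shc: basal phosphorylation only
                rowsSpec("01", 1, 1), rowsSpec("10", 1, 1),
                rowsSpec("11", y = "1")),    # mutual-exclusion row, logical view only
    `7` = rowsSpec("1", 1, 1),
    `8` = rbind(rowsSpec("0", 0.01, 1), rowsSpec("1", 1, 1)),
    `9` = rowsSpec("1", 1, 1),
    `10` = rbind(rowsSpec("0", 0.01, 1), rowsSpec("1", 1, 1)),
    `11` = rbind(rowsSpec("0", 0.01, 1), rowsSpec("1", 1, 1)),
    `12` = rowsSpec("1", 1, 1),
    `13` = rbind(rowsSpec("0", 0.1, 1),      # monomeric receptor binds ligand
                 rowsSpec("1", 1, 1)),       # dimer binds more strongly
    `14` = rbind(rowsSpec("00", 0.001, 1),   # two ligand-free monomers: negligible
                 rowsSpec("01", 0.01, 1), rowsSpec("11", 1, 1)),
    `15` = rbind(rowsSpec("0", 0.001, 1), rowsSpec("1", 1, 1)),
    `16` = rbind(rowsSpec("0", 0.001, 1), rowsSpec("1", 1, 1)),
    `17` = rowsSpec("1", 1, 1),
    `18` = rowsSpec("1", 1, 1)
  ))
}
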