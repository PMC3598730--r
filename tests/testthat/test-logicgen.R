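test_that("small-example L-nodes and correspondence match the construction", {
  p <- buildSmallExample()
  ln <- deriveLNodes(p)
  expect_setequal(ln$nodes$id[ln$nodes$role == "basal"], c("A", "B", "R"))
  expect_setequal(ln$nodes$id[ln$nodes$role == "site"],
                  c("A.b1", "B.b1", "R.b1", "R.p1", "R.p2"))
  cmap <- stats::setNames(ln$correspondsTo$lnode, ln$correspondsTo$pnode)
  expect_equal(cmap[["1"]], "R.b1")
  expect_equal(cmap[["2"]], "R.p1")
  expect_equal(cmap[["3"]], "R.p2")
  expect_equal(cmap[["4"]], "B.b1")
  expect_equal(ln$lcorresponds, data.frame(from = "A.b1", to = "R.b1"))
})

test_that("one molecule binding two pre-modified sites forces an auxiliary node", {
  p <- buildSharedPartnerExample()
  ln <- deriveLNodes(p)
  expect_true(any(ln$nodes$role == "auxiliary"))
  expect_equal(ln$nodes$id[ln$nodes$role == "auxiliary"], "A.b1#4")
  # the correspondence stays one-to-one
  expect_equal(anyDuplicated(ln$correspondsTo$lnode), 0L)
  expect_equal(nrow(ln$correspondsTo), nrow(processNodes(p)))
})

test_that("a single modification process yields basal plus one site node", {
  mols <- list(A = "s1")
  pr <- data.frame(id = 1L, type = "modification", mol1 = "A", site1 = "s1",
                   mol2 = NA_character_, site2 = NA_character_,
                   reversible = TRUE, stringsAsFactors = FALSE)
  skel <- Pim(mols, pr, NULL, list(), list(t1 = 0.01, t2 = 0.1))
  p <- pimod:::fillTables(skel, list(`1` = data.frame(
    ctx = "", kfw = 1, kbw = 1, y = NA_character_)))
  ln <- deriveLNodes(p)
  expect_equal(sort(ln$nodes$id), c("A", "A.s1"))
})

test_that("small-example interaction graph has the documented edges", {
  g <- deriveInteractionGraph(buildSmallExample())
  act <- lEdges(g)[lEdges(g)$type == "activating", ]
  uns <- lEdges(g)[lEdges(g)$type == "unsigned", ]
  expect_equal(nrow(act), 6L)
  expect_setequal(paste(act$from, act$to),
                  c("A A.b1", "R R.b1", "R R.p1", "R R.p2", "B B.b1",
                    "A.b1 R.b1"))
  expect_equal(nrow(uns), 4L)
  expect_setequal(paste(uns$from, uns$to),
                  c("R.b1 R.p1", "R.p1 R.p2", "R.p2 R.p1", "R.p1 B.b1"))
})

test_that("unsigned edges are in bijection with the influences", {
  for (s in 1:40) {
    p <- randomPim(seed = s)
    g <- deriveInteractionGraph(p)
    uns <- lEdges(g)[lEdges(g)$type == "unsigned", ]
    expect_equal(nrow(uns), nrow(influences(p)), info = paste("seed", s))
  }
})

test_that("degradation adds a delay-flagged inhibiting edge onto basal", {
  g <- deriveInteractionGraph(buildDegradationExample())
  inh <- lEdges(g)[lEdges(g)$type == "inhibiting", ]
  expect_equal(nrow(inh), 1L)
  expect_equal(inh$from, "A.deg3")
  expect_equal(inh$to, "A")
  expect_true(inh$delay)
})

test_that("gate synthesis reproduces the expected small-example gates", {
  p <- buildSmallExample()
  m <- deriveLogicalModel(p)
  gs <- gateFunctions(m)
  # all-or-none identity gate: B.b1 active iff R.p1 modified and B present;
  # R.p1 enters through the unsigned edge as the table literal
  expect_equal(gs[["B.b1"]]$act, "B")
  expect_equal(gs[["B.b1"]]$terms, list("R.p1"))
  # OR gate on R.p1, conjoined with basal R
  expect_equal(gs[["R.p1"]]$act, "R")
  expect_setequal(vapply(gs[["R.p1"]]$terms, paste, character(1),
                         collapse = "&"), c("R.b1", "R.p2"))
  # free partner site passes the basal value
  expect_equal(gs[["A.b1"]]$act, "A")
  # basal nodes are inputs
  expect_true(isTRUE(gs[["R"]]$input))
})

test_that("gates agree with their source truth tables on defined rows", {
  for (s in 1:60) {
    p <- randomPim(seed = s)
    m <- deriveLogicalModel(p)
    cmap <- m@graph@correspondsTo
    for (k in seq_len(nrow(cmap))) {
      tt <- truthTable(p, cmap$pnode[k])
      g <- gateFunctions(m)[[cmap$lnode[k]]]
      n <- length(tt@inputs)
      for (j in seq_len(nrow(tt@rows))) {
        if (tt@rows$y[j] == "*") next
        bits <- if (n) strsplit(tt@rows$ctx[j], "")[[1]] == "1" else logical(0)
        assign <- as.list(stats::setNames(bits, g$inputs[seq_len(n)]))
        got <- oracleEvalTerms(g$terms, assign)
        expect_equal(got, tt@rows$y[j] == "1",
                     info = sprintf("seed %d node %d ctx %s",
                                    s, cmap$pnode[k], tt@rows$ctx[j]))
      }
    }
  }
})

test_that("unknown rows make an ITT gate under the conservative policy", {
  p <- buildHomodimerExample()
  p@tables[["2"]]@rows$kfw[3] <- 0.05   # equal-monomer 11 row becomes *
  m <- deriveLogicalModel(p)
  g <- gateFunctions(m)[[ "A.d" ]]
  expect_true(g$itt)
  expect_equal(g$terms, list())        # only the 0 row remains defined
  m1 <- deriveLogicalModel(p, ittPolicy = "as1")
  expect_equal(gateFunctions(m1)[["A.d"]]$terms, list("A.p1"))
})

test_that("both orientations give the same steady states away from the pair", {
  for (p in list(buildSmallExample(), buildEgfInsulin())) {
    m1 <- deriveLogicalModel(p, orientation = "second")
    m2 <- deriveLogicalModel(p, orientation = "first")
    modSites <- unique(with(processNodes(p),
                            paste(mol1, site1, sep = ".")[type == "modification"]))
    basal <- names(molecules(p))
    for (offSet in list(character(0), basal[1])) {
      s1 <- steadyState(m1, makeScenario(m1, off = offSet))
      s2 <- steadyState(m2, makeScenario(m2, off = offSet))
      expect_identical(s1[c(modSites, basal)], s2[c(modSites, basal)],
                       info = paste("off:", paste(offSet, collapse = ",")))
    }
  }
})

test_that("threshold variants nest: lower subset of default subset of higher", {
  sw <- sweepThresholds(buildEgfInsulin(),
                        list(c(0.001, 0.01), c(0.01, 0.1), c(0.1, 0.25)))
  key <- function(df) paste(df$from, df$to, sep = "->")
  e <- lapply(sw$edges, key)
  expect_true(all(e[[1]] %in% e[[2]]))
  expect_true(all(e[[2]] %in% e[[3]]))
  # the high-threshold model gains the mutual inhibition of the two
  # insulin binding sites, realized as negative literals
  mUp <- sw$models[[3]]
  g <- gateFunctions(mUp)[["ir.b_ins"]]
  expect_true("!ir.b_ins2" %in% unlist(g$terms))
})

test_that("logic export is deterministic and counts edges correctly", {
  m <- deriveLogicalModel(buildSmallExample())
  out <- exportLogic(m)
  expect_identical(out, exportLogic(m))
  expect_length(out$sif, 10L)  # 6 activating + 4 unsigned
  signs <- vapply(strsplit(out$sif, "\t"), `[[`, character(1), 2)
  expect_true(all(signs %in% c("-1", "0", "1")))
  expect_equal(out$gates[1], "node\tterm\tliterals\titt")
  # every non-input gate line's literals reference known nodes
  ids <- lNodes(m)$id
  for (ln in out$gates[-1]) {
    f <- strsplit(ln, "\t")[[1]]
    if (f[3] %in% c("INPUT", "TRUE", "FALSE")) next
    lits <- sub("^!", "", strsplit(f[3], ",")[[1]])
    expect_true(all(lits %in% ids))
  }
  dirOut <- file.path(tempdir(), "pimod-export-test")
  exportLogic(m, dir = dirOut)
  expect_true(all(file.exists(file.path(dirOut,
                                        c("model.sif", "gates.tsv", "model.dot")))))
})
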