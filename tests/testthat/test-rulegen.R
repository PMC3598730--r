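test_that("small-example rules match the expected patterns", {
  p <- buildSmallExample()
  r1 <- rulesForNode(p, 1)
  expect_length(r1, 1)
  expect_equal(r1[[1]]$text, "A(b1) + R(b1) <-> A(b1!1).R(b1!1) kf_n1, kb_n1")

  r2 <- rulesForNode(p, 2)
  expect_length(r2, 4)
  # context 00: nothing bound, nothing modified except the center change
  expect_equal(r2[[1]]$lhs, "R(b1,p1~U,p2~U)")
  expect_equal(r2[[1]]$rhs, "R(b1,p1~M,p2~U)")
  # context 11: A attached through its bond, p2 modified
  expect_equal(r2[[4]]$lhs, "R(b1!2,p1~U,p2~M).A(b1!2)")

  # all-or-none pruning: binding of B only to the modified site
  r4 <- rulesForNode(p, 4)
  expect_length(r4, 1)
  expect_equal(r4[[1]]$text,
               "B(b1) + R(p1~M) <-> B(b1!1).R(p1~M!1) kf_n4_c1, kb_n4_c1")
})

test_that("context sites are identical on both rule sides", {
  for (p in list(buildSmallExample(), buildEgfInsulin(),
                 buildCompetingBindingExample())) {
    for (i in processNodes(p)$id) {
      cs <- centerSitesOf(p, i)
      for (r in rulesForNode(p, i)) {
        expect_identical(contextTokens(r$lhs, cs), contextTokens(r$rhs, cs),
                         info = sprintf("node %d ctx %s", i, r$ctx))
      }
    }
  }
})

test_that("exported BNGL passes the grammar check and is deterministic", {
  for (p in list(buildSmallExample(), buildEgfInsulin())) {
    b <- exportBngl(p)
    expect_true(isTRUE(checkBnglGrammar(b)))
    expect_identical(b, exportBngl(p))
  }
  for (s in c(3, 17, 31)) {
    b <- exportBngl(randomPim(seed = s))
    expect_true(isTRUE(checkBnglGrammar(b)), info = paste("seed", s))
  }
})

test_that("rule totals equal the sum of admissible contexts", {
  for (p in list(buildSmallExample(), buildEgfInsulin())) {
    expected <- sum(vapply(processNodes(p)$id, function(i) {
      oracleContextCount(p, i)
    }, numeric(1)))
    expect_equal(bnglRuleCount(exportBngl(p)), expected)
  }
  expect_equal(bnglRuleCount(exportBngl(buildSmallExample())), 8L)
  expect_equal(bnglRuleCount(exportBngl(buildEgfInsulin())), 36L)
})

test_that("homodimerization rules halve the symmetric forward rate", {
  p <- buildHomodimerExample()
  rr <- rulesForNode(p, 2)
  expect_equal(vapply(rr, `[[`, character(1), "ctx"), c("00", "01", "11"))
  expect_equal(vapply(rr, `[[`, numeric(1), "kfw"), c(0.5 * 0.005, 0.05, 0.5))
  expect_equal(rr[[2]]$lhs, "A(p1~U,d) + A(p1~M,d)")
  expect_equal(rr[[2]]$rhs, "A(p1~U,d!1).A(p1~M,d!1)")
})

test_that("degradation emits irreversible deletion rules", {
  p <- buildDegradationExample()
  rr <- rulesForNode(p, 3)
  expect_length(rr, 2)
  expect_false(rr[[1]]$reversible)
  expect_equal(rr[[2]]$text, "A(ub~M) -> 0 kf_n3_c1")
  expect_true(isTRUE(checkBnglGrammar(exportBngl(p))))
})

test_that("molecule types and seed species declare modification states", {
  b <- exportBngl(buildSmallExample())
  expect_true("  R(b1,p1~U~M,p2~U~M)" %in% b)
  expect_true("  R(b1,p1~U,p2~U) 1" %in% b)
  expect_true("  A(b1) 1" %in% b)
})

test_that("dropping a molecule removes its processes and collapses tables", {
  p <- buildSmallExample()

  noB <- dropMolecule(p, "B")
  expect_true(validatePim(noB)$ok)
  expect_false(4L %in% processNodes(noB)$id)
  expect_equal(bnglRuleCount(exportBngl(noB)), 7L)  # 1 + 4 + 2
  expect_false(any(grepl("B\\(", exportBngl(noB))))

  noA <- dropMolecule(p, "A")
  expect_true(validatePim(noA)$ok)
  expect_false(1L %in% processNodes(noA)$id)
  # node 2 collapses to the contexts with process 1 fixed at 0
  expect_equal(parameterTable(noA, 2)@rows$ctx, c("0", "1"))
  expect_equal(parameterTable(noA, 2)@rows$kbw, c(100, 1))
  expected <- sum(vapply(processNodes(noA)$id, function(i) {
    oracleContextCount(noA, i)
  }, numeric(1)))
  expect_equal(bnglRuleCount(exportBngl(noA)), expected)

  # dropping cascades through all-or-none prerequisites
  noR <- dropMolecule(buildEgfInsulin(), "ir")
  expect_true(validatePim(noR)$ok)
  expect_false(any(c(1:5, 9) %in% processNodes(noR)$id))
  expect_error(dropMolecule(p, "nosuch"), "unknown molecule")
})

test_that("drop of an uninvolved molecule only shrinks the molecule list", {
  p <- buildSmallExample()
  p@molecules$X <- "s1"
  v <- validatePim(p)  # orphan site is a warning only
  expect_true(v$ok)
  q <- dropMolecule(p, "X")
  expect_true(pimEqual(q, buildSmallExample()))
})
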