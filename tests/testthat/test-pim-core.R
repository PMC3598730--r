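test_that("shipped models pass validation cleanly", {
  expect_true(validatePim(buildSmallExample())$ok)
  expect_length(validatePim(buildSmallExample())$warnings, 0)
  expect_true(validatePim(buildEgfInsulin())$ok)
  expect_length(validatePim(buildEgfInsulin())$warnings, 0)
})

test_that("validation rejects single-field mutations of stated invariants", {
  base <- buildSmallExample()

  p <- base; p@thresholds$t2 <- p@thresholds$t1
  expect_match(paste(validatePim(p)$errors, collapse = " "),
               "not strictly ordered")

  p <- base; p@tables[["2"]]@rows$kfw[1] <- 0
  expect_match(paste(validatePim(p)$errors, collapse = " "),
               "forward rate constant must be nonzero")

  p <- base; p@processes$id[2] <- 1L
  expect_false(validatePim(p)$ok)

  p <- base; p@processes$site1[2] <- "nosuch"
  expect_match(paste(validatePim(p)$errors, collapse = " "), "unresolved")

  p <- base; p@tables[["2"]]@rows <- p@tables[["2"]]@rows[-1, ]
  expect_match(paste(validatePim(p)$errors, collapse = " "), "missing row")

  p <- base
  p@processes <- rbind(p@processes, data.frame(
    id = 9L, type = "degradation", mol1 = "A", site1 = NA_character_,
    mol2 = NA_character_, site2 = NA_character_, reversible = TRUE))
  expect_match(paste(validatePim(p)$errors, collapse = " "), "irreversible")

  p <- base
  p@influences <- rbind(p@influences,
                        data.frame(source = 2L, target = 2L, kind = "plain"))
  expect_match(paste(validatePim(p)$errors, collapse = " "), "self-loop")

  # a site no process touches is a warning, not an error
  p <- base; p@molecules$A <- c("b1", "lonely")
  v <- validatePim(p)
  expect_true(v$ok)
  expect_match(paste(v$warnings, collapse = " "), "lonely")
})

test_that("predecessors come back ascending and kind-tagged", {
  p <- buildSmallExample()
  expect_equal(predecessorsOf(p, 2),
               data.frame(id = c(1L, 3L), kind = c("plain", "plain")))
  expect_equal(nrow(predecessorsOf(p, 1)), 0L)
  expect_equal(predecessorsOf(p, 4),
               data.frame(id = 2L, kind = "all_or_none"))
  expect_error(predecessorsOf(p, 99), "unknown process")
})

test_that("mutual exclusion is detected for competing center-site bindings only", {
  comp <- buildCompetingBindingExample()
  expect_equal(mutuallyExclusiveInputs(comp, 3),
               data.frame(a = 1L, b = 2L))
  expect_equal(nrow(mutuallyExclusiveInputs(buildSmallExample(), 2)), 0L)
  # a ligand site shared across two receptor domains is not exclusive:
  # each binding attaches its own ligand copy
  egf <- buildEgfInsulin()
  expect_equal(nrow(mutuallyExclusiveInputs(egf, 3)), 0L)
  expect_equal(mutuallyExclusiveInputs(egf, 6),
               data.frame(a = 5L, b = 17L))
})

test_that("context enumeration matches the stated examples", {
  p <- buildSmallExample()
  expect_equal(enumerateContexts(p, 2), c("00", "01", "10", "11"))
  expect_equal(enumerateContexts(p, 4), "1")
  expect_equal(enumerateContexts(p, 1), "")
  expect_equal(enumerateContexts(buildHomodimerExample(), 2),
               c("00", "01", "11"))
  comp <- buildCompetingBindingExample()
  expect_equal(enumerateContexts(comp, 3), c("00", "01", "10"))
})

test_that("context counts equal the brute-force oracle on random models", {
  for (s in 1:60) {
    p <- randomPim(seed = s)
    for (i in processNodes(p)$id) {
      expect_equal(length(enumerateContexts(p, i)), oracleContextCount(p, i),
                   info = sprintf("seed %d node %d", s, i))
    }
  }
})

test_that("enumeration and predecessor order are deterministic", {
  p <- buildEgfInsulin()
  for (i in processNodes(p)$id) {
    expect_identical(enumerateContexts(p, i), enumerateContexts(p, i))
    expect_identical(predecessorsOf(p, i), predecessorsOf(p, i))
  }
})

test_that("equilibrium constant is the forward/backward quotient", {
  expect_equal(equilibriumConstant(list(kfw = 1, kbw = 10)), 0.1)
  expect_equal(equilibriumConstant(list(kfw = 5, kbw = 5)), 1.0)
  expect_error(equilibriumConstant(list(kfw = 1, kbw = NA_real_)),
               "irreversible")
  expect_error(equilibriumConstant(list(kfw = 1, kbw = 0)), "zero")
})
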