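smallModel <- deriveLogicalModel(buildSmallExample())

test_that("single evaluation follows the Kleene truth tables", {
  m <- smallModel
  ids <- lNodes(m)$id
  st <- stats::setNames(rep("*", length(ids)), ids)
  st[c("A", "B", "R")] <- "1"
  # B.b1 = B AND R.p1: AND(1, *) = *
  e1 <- evaluateState(m, st, fixed = c("A", "B", "R"))
  expect_equal(e1[["B.b1"]], "*")
  st2 <- st; st2[["R.p1"]] <- "0"
  expect_equal(evaluateState(m, st2, fixed = c("A", "B", "R"))[["B.b1"]], "0")
  st3 <- st; st3[["R.p1"]] <- "1"
  expect_equal(evaluateState(m, st3, fixed = c("A", "B", "R"))[["B.b1"]], "1")
  # a fixed point stays fixed
  ss <- `attr<-`(steadyState(m, makeScenario(m)), "iterations", NULL)
  expect_identical(evaluateState(m, ss, fixed = c("A", "B", "R")), ss)
})

test_that("steady state resolves the whole small example when all basal on", {
  ss <- steadyState(smallModel, makeScenario(smallModel))
  sites <- c("A.b1", "R.b1", "R.p1", "R.p2", "B.b1")
  expect_true(all(ss[sites] == "1"))
  expect_lte(attr(ss, "iterations"), length(lNodes(smallModel)$id) + 1L)
})

test_that("absent molecules zero their sites along activating chains", {
  ss <- steadyState(smallModel, makeScenario(smallModel, off = "A"))
  expect_equal(ss[["A.b1"]], "0")
  expect_equal(ss[["R.b1"]], "0")
  # R.p1 still reachable through R.p2 (OR gate)
  expect_equal(ss[["R.p1"]], "1")
  # knocking out B affects only B's own site, nothing upstream
  sB <- steadyState(smallModel, makeScenario(smallModel, off = "B"))
  s0 <- steadyState(smallModel, makeScenario(smallModel))
  expect_equal(sB[["B.b1"]], "0")
  up <- setdiff(names(s0), c("B", "B.b1"))
  expect_identical(sB[up], s0[up])
})

test_that("steady state terminates within the node-count bound on random models", {
  for (s in 1:40) {
    p <- randomPim(seed = s)
    m <- deriveLogicalModel(p)
    ss <- steadyState(m, makeScenario(m))
    expect_lte(attr(ss, "iterations"), length(lNodes(m)$id) + 1L)
    ss0 <- `attr<-`(ss, "iterations", NULL)
    expect_identical(evaluateState(m, ss0, fixed = names(makeScenario(m)$fixed)),
                     ss0)
  }
})

test_that("delay-flagged degradation edges are excluded from steady state", {
  m <- deriveLogicalModel(buildDegradationExample())
  ss <- steadyState(m, makeScenario(m))
  # degradation is active, yet basal A stays at its input value
  expect_equal(ss[["A.deg3"]], "1")
  expect_equal(ss[["A"]], "1")
  expect_equal(gateFunctions(m)[["A"]]$delayed, "A.deg3")
})

test_that("equivalence classes partition the varying nodes", {
  m <- deriveLogicalModel(buildEgfInsulin())
  sc <- makeScenario(m, undefined = c("ins", "egf"))
  ec <- equivalenceClasses(m, sc, undefined = c("ins", "egf"))
  all <- lNodes(m)$id
  grouped <- c(unlist(ec$classes, use.names = FALSE), ec$constant)
  expect_setequal(grouped, all)
  expect_equal(anyDuplicated(grouped), 0L)
  expect_equal(nrow(ec$completions), 4L)
  # zero undefined inputs: everything constant, no classes
  ec0 <- equivalenceClasses(m, makeScenario(m), undefined = character(0))
  expect_length(ec0$classes, 0)
  expect_setequal(ec0$constant, all)
  expect_error(equivalenceClasses(m, sc, undefined = sprintf("x%d", 1:17)),
               "too many")
})

test_that("intervention sets block the target and are inclusion-minimal", {
  m <- deriveLogicalModel(buildEgfInsulin())
  sc <- makeScenario(m, on = "ins", off = "egf")
  mis <- minimalInterventionSets(m, sc, target = "grb2.b_shc", kmax = 2)
  expect_gt(length(mis), 0)
  for (s in mis) {
    st <- steadyState(m, sc, interventions = s)
    expect_equal(st[["grb2.b_shc"]], "0", info = paste(s, collapse = ","))
    # removing any element un-blocks the target
    for (drop in seq_along(s)) {
      st2 <- steadyState(m, sc, interventions = s[-drop])
      expect_equal(st2[["grb2.b_shc"]], "1",
                   info = paste("minus", s[drop]))
    }
  }
  # antichain under inclusion
  if (length(mis) > 1) {
    for (i in seq_along(mis)) for (j in seq_along(mis)) {
      if (i != j) expect_false(all(mis[[i]] %in% mis[[j]]))
    }
  }
})

test_that("for a target that is itself an input, its knockout is the unique set", {
  m <- smallModel
  sc <- makeScenario(m)
  mis <- minimalInterventionSets(m, sc, target = "A", kmax = 2,
                                 candidates = lNodes(m)$id)
  expect_equal(mis, list("A"))
})
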