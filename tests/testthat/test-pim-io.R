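test_that("document round-trip is the identity on the shipped models", {
  for (p in list(buildSmallExample(), buildEgfInsulin())) {
    doc <- writePim(p)
    expect_true(pimEqual(readPim(doc), p))
    # canonical serialization is byte-stable
    expect_identical(writePim(readPim(doc)), doc)
  }
})

test_that("document round-trip holds on random models", {
  for (s in 1:200) {
    p <- randomPim(seed = s)
    expect_true(pimEqual(readPim(writePim(p)), p), info = paste("seed", s))
  }
})

test_that("the shipped document files match the builders", {
  f1 <- system.file("extdata", "small-example.yaml", package = "pimod")
  f2 <- system.file("extdata", "egf-insulin-synthetic.yaml", package = "pimod")
  expect_true(nzchar(f1) && nzchar(f2))
  expect_true(pimEqual(readPimFile(f1), buildSmallExample()))
  expect_true(pimEqual(readPimFile(f2), buildEgfInsulin()))
})

test_that("reader reports degenerate documents", {
  expect_error(readPim("molecules: []\nprocesses: []\n"), "no molecules")
  expect_error(readPim("molecules:\n  - name: A\n    sites: [b1]\nprocesses: []\n"),
               "no processes")
  expect_error(readPim(paste0("molecules:\n  - name: A\n    sites: [b1]\n",
                              "processes:\n  - id: 1\n    type: binding\n",
                              "    sites: [A.b1]\n")),
               "expected 2")
})

test_that("bidirectional influence sugar expands to two plain edges", {
  doc <- paste(
    "molecules:",
    "  - {name: A, sites: [s1]}",
    "  - {name: B, sites: [s1]}",
    "processes:",
    "  - {id: 1, type: modification, sites: [A.s1], reversible: true}",
    "  - {id: 2, type: binding, sites: [A.s1, B.s1], reversible: true}",
    "influences:",
    "  - {source: 1, target: 2, kind: bidirectional}",
    "parameters:",
    "  - node: 1",
    "    rows:",
    "      - {ctx: [0], kfw: 1.0, kbw: 1.0}",
    "      - {ctx: [1], kfw: 1.0, kbw: 1.0}",
    "  - node: 2",
    "    rows:",
    "      - {ctx: [0], kfw: 1.0, kbw: 1.0}",
    "      - {ctx: [1], kfw: 1.0, kbw: 1.0}",
    "thresholds: {t1: 0.01, t2: 0.1}",
    sep = "\n")
  p <- readPim(doc)
  expect_equal(nrow(influences(p)), 2L)
  expect_setequal(paste(influences(p)$source, influences(p)$target),
                  c("1 2", "2 1"))
  expect_true(all(influences(p)$kind == "plain"))
  expect_true(validatePim(p)$ok)
})

test_that("small example has the documented structure and rule counts", {
  p <- buildSmallExample()
  expect_length(molecules(p), 3)
  expect_equal(nrow(processNodes(p)), 4L)
  perNode <- vapply(1:4, function(i) length(rulesForNode(p, i)), integer(1))
  expect_equal(perNode, c(1L, 4L, 2L, 1L))
  expect_equal(bnglRuleCount(exportBngl(p)), 8L)
})

test_that("EGF-insulin model has 18 processes and passes validation", {
  p <- buildEgfInsulin()
  expect_equal(nrow(processNodes(p)), 18L)
  expect_true(validatePim(p)$ok)
  expect_equal(sum(grepl("^- id:|^  id:", strsplit(writePim(p), "\n")[[1]])), 18L)
})

test_that("random generator is seed-deterministic and restores RNG state", {
  set.seed(1234)
  before <- stats::runif(1)
  set.seed(1234)
  a <- randomPim(seed = 7)
  after <- stats::runif(1)
  expect_identical(before, after)  # caller RNG untouched
  b <- randomPim(seed = 7)
  expect_true(pimEqual(a, b))
  expect_false(pimEqual(a, randomPim(seed = 8)))
})

test_that("random models are structurally valid", {
  for (s in 201:400) {
    v <- validatePim(randomPim(seed = s))
    expect_true(v$ok, info = paste("seed", s, paste(v$errors, collapse = ";")))
  }
})
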