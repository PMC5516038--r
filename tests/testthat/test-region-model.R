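test_that("ontology construction derives depths and enforces a single root", {
  ont <- RegionOntology(id = c("GM", "Tel", "DiE", "Cx"),
                        parent = c(NA, "GM", "GM", "Tel"))
  expect_equal(regionDepth(ont, "GM"), 1L)
  expect_equal(regionDepth(ont, "Cx"), 3L)
  expect_equal(rootRegion(ont), "GM")
  expect_setequal(regionChildren(ont, "GM"), c("Tel", "DiE"))
  expect_setequal(regionDescendants(ont, "Tel"), c("Tel", "Cx"))
  expect_error(RegionOntology(id = c("a", "b"), parent = c(NA, "zz")),
               "unreachable")
  expect_error(methods::validObject(methods::new(
    "RegionOntology",
    nodes = data.frame(id = c("a", "a"), name = "a",
                       parent = c(NA, "a"), depth = c(1L, 2L)))),
    "unique")
})

test_that("loadStudy keeps left-hemisphere samples and validates regions", {
  dir <- withr::local_tempdir()
  st <- tinyStudy()
  writeStudy(st, dir)
  sheet <- readTsv(file.path(dir, "samples.tsv"))
  sheet$hemisphere[1:2] <- "R"
  writeTsv(sheet, file.path(dir, "samples.tsv"))
  st2 <- loadStudy(file.path(dir, "expression.tsv"),
                   file.path(dir, "present.tsv"),
                   file.path(dir, "samples.tsv"),
                   file.path(dir, "ontology.json"))
  expect_equal(ncol(st2), ncol(st) - 2)
  expect_true(all(sampleData(st2)$hemisphere == "L"))

  sheet$hemisphere <- "L"
  sheet$region_id[3] <- "nowhere"
  writeTsv(sheet, file.path(dir, "samples.tsv"))
  expect_error(loadStudy(file.path(dir, "expression.tsv"),
                         file.path(dir, "present.tsv"),
                         file.path(dir, "samples.tsv"),
                         file.path(dir, "ontology.json")),
               "nowhere")
})

test_that("study TSV round-trip reproduces values exactly", {
  dir <- withr::local_tempdir()
  st <- tinyStudy()
  writeStudy(st, dir)
  st2 <- loadStudy(file.path(dir, "expression.tsv"),
                   file.path(dir, "present.tsv"),
                   file.path(dir, "samples.tsv"),
                   file.path(dir, "ontology.json"))
  expect_equal(exprsValues(st2), exprsValues(st))
  expect_equal(presentCalls(st2), presentCalls(st))
  # load -> write reproduces the files byte-identically
  dir2 <- withr::local_tempdir()
  writeStudy(st2, dir2)
  for (f in c("expression.tsv", "present.tsv", "samples.tsv"))
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)))
})

test_that("samplesForRegion pools descendant sub-regions", {
  st <- tinyStudy(nPerSub = 3)
  expect_length(samplesForRegion(st, "Aa"), 3)
  expect_length(samplesForRegion(st, "A"), 6)
  expect_setequal(samplesForRegion(st, "GM"), sampleData(st)$sample_id)
  expect_error(samplesForRegion(st, "nope"), "unknown region")
})

test_that("replicate collapse takes medians, majority present, idempotent", {
  ont <- RegionOntology(id = c("GM", "A"), parent = c(NA, "GM"))
  samples <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                        donor_id = c("d1", "d1", "d1", "d2"),
                        region_id = "A", hemisphere = "L",
                        structure_id = c("x", "x", "x", "x"))
  em <- matrix(c(1, 2, 9, 5), 1, 4,
               dimnames = list("g1", samples$sample_id))
  pm <- matrix(c(TRUE, FALSE, FALSE, TRUE), 1, 4,
               dimnames = dimnames(em))
  st <- BrainExpressionStudy(em, pm, samples, ont)
  cl <- collapseReplicates(st)
  expect_equal(ncol(cl), 2)               # one per (donor, structure)
  expect_equal(unname(exprsValues(cl)[1, 1]), 2)   # median of 1,2,9
  expect_false(presentCalls(cl)[1, 1])    # 1/3 present -> majority FALSE
  expect_true(presentCalls(cl)[1, 2])
  cl2 <- collapseReplicates(cl)
  expect_equal(exprsValues(cl2), exprsValues(cl))

  # even-sized group: median = mean of central values
  samples2 <- samples[1:2, ]
  em2 <- matrix(c(3, 5), 1, 2, dimnames = list("g1", c("s1", "s2")))
  pm2 <- matrix(TRUE, 1, 2, dimnames = dimnames(em2))
  st2 <- BrainExpressionStudy(em2, pm2, samples2, ont)
  expect_equal(unname(exprsValues(collapseReplicates(st2))[1, 1]), 4)
})

test_that("probe collapse takes the median of probe medians per sample", {
  ont <- RegionOntology(id = c("GM", "A"), parent = c(NA, "GM"))
  samples <- data.frame(sample_id = "s1", donor_id = "d1",
                        region_id = "A", hemisphere = "L",
                        structure_id = "x")
  em <- matrix(c(3, 5), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  pm <- matrix(TRUE, 2, 1, dimnames = dimnames(em))
  st <- BrainExpressionStudy(em, pm, samples, ont)
  cl <- collapseProbes(st, c(p1 = "geneA", p2 = "geneA"))
  expect_equal(unname(exprsValues(cl)["geneA", 1]), 4)
})

test_that("eligibleRegions counts collapsed samples against the threshold", {
  st <- tinyStudy(nPerSub = 3)     # 12 collapsed samples at the root
  expect_setequal(eligibleRegions(st, 1),
                  c("GM", "A", "B", "Aa", "Ab", "Ba", "Bb"))
  expect_setequal(eligibleRegions(st, 6), c("GM", "A", "B"))
  expect_setequal(eligibleRegions(st, 12), "GM")
  expect_length(eligibleRegions(st, 13), 0)
})
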