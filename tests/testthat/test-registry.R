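test_that("packaged registry has the published index compositions", {
  reg <- loadRegistry()
  expect_equal(nrow(indexItems(reg, "infrastructure")), 14L)
  expect_equal(nrow(indexItems(reg, "private_market")), 26L)
  expect_equal(nrow(indexItems(reg, "public_quality")), 18L)
  pm <- indexItems(reg, "private_market")
  expect_equal(sum(pm$derived), 1L)
  expect_equal(pm$item_id[pm$derived], "inspections")
  expect_setequal(unique(pm$aspect),
                  c("legal_framework", "supply_chain", "pharmacovigilance"))
  # infrastructure / public-quality items carry no aspect tag
  expect_true(all(is.na(indexItems(reg, "infrastructure")$aspect)))
})

test_that("a registry omitting an item fails validation naming the id", {
  reg <- loadRegistry()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  broken <- reg
  broken@items <- reg@items[!(reg@items$index == "infrastructure" &
                                reg@items$item_id == "5.05.03"), ]
  # bypass the constructor to write the broken set, then load it back
  out <- list()
  for (ix in c("infrastructure", "private_market", "public_quality")) {
    sub <- broken@items[broken@items$index == ix, ]
    out[[ix]] <- list(items = lapply(seq_len(nrow(sub)), function(k) {
      item <- list(id = sub$item_id[k], label = sub$label[k])
      if (!is.na(sub$aspect[k])) item$aspect <- sub$aspect[k]
      if (sub$derived[k]) item$derived <- list(sources = sub$sources[[k]])
      item
    }))
  }
  yaml::write_yaml(out, tmp)
  expect_error(loadRegistry(tmp), "5\\.05\\.03")
})

test_that("malformed registry config errors name the offending block", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(infrastructure = list(items = list(
    list(id = "a", label = "b")))), tmp)
  expect_error(loadRegistry(tmp), "private_market")
  yaml::write_yaml(list(infrastructure = list(wrong = 1),
                        private_market = list(items = list()),
                        public_quality = list(items = list())), tmp)
  expect_error(loadRegistry(tmp), "infrastructure")
})

test_that("registry round-trips through write and load", {
  reg <- loadRegistry()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeRegistry(reg, tmp)
  reloaded <- loadRegistry(tmp)
  expect_equal(reloaded@items$item_id, reg@items$item_id)
  expect_equal(reloaded@items$label, reg@items$label)
  expect_equal(reloaded@items$aspect, reg@items$aspect)
  expect_equal(reloaded@items$sources, reg@items$sources)
})

test_that("inspection composite follows the stated coding rules", {
  # all segments within three years
  expect_equal(buildInspectionsComposite(c(3, 3, 3), "regular"), 1L)
  # one segment inspected at least yearly rescues the 'regular' coding
  expect_equal(buildInspectionsComposite(c(5, 5, 1), "regular"), 1L)
  expect_equal(buildInspectionsComposite(c(5, 5, 1), "annual"), 0L)
  expect_equal(buildInspectionsComposite(c(1, 1, 1), "annual"), 1L)
  expect_equal(buildInspectionsComposite(c(4, 3, 3), "regular"), 0L)
  # missing propagates regardless of the other segments
  expect_true(is.na(buildInspectionsComposite(c(NA, 3, 1), "regular")))
  expect_error(buildInspectionsComposite(c(0, 3, 3), "regular"), "positive")
})

test_that("composite matches brute-force enumeration over a frequency grid", {
  grid <- expand.grid(m = c(0.5, 1, 2, 3, 4), r = c(0.5, 1, 2, 3, 4),
                      d = c(0.5, 1, 2, 3, 4))
  for (variant in c("regular", "annual")) {
    got <- buildInspectionsComposite(as.matrix(grid), variant)
    want <- mapply(bruteForceComposite, grid$m, grid$r, grid$d,
                   MoreArgs = list(variant = variant))
    expect_equal(got, unname(want))
  }
})

test_that("assembleResponses validates, orders and derives columns", {
  reg <- loadRegistry()
  items <- indexItems(reg, "infrastructure")
  m <- matrix(0L, 3, 14, dimnames = list(c("AAA", "BBB", "CCC"),
                                         items$item_id))
  m[, 1] <- 1L  # avoid all-missing/constant degenerate validation
  m[1, ] <- 1L
  rs <- assembleResponses(rawSurveyFrame(m), reg, "infrastructure")
  expect_s4_class(rs, "ResponseSet")
  expect_equal(dim(responseMatrix(rs)), c(3L, 14L))
  expect_equal(itemIds(rs), items$item_id)
  # idempotent on an already-assembled object
  expect_identical(assembleResponses(rs, reg, "infrastructure"), rs)

  # non-binary observed cell is a coding error with coordinates
  bad <- rawSurveyFrame(m)
  bad[2, "5.01.02"] <- 2
  expect_error(assembleResponses(bad, reg, "infrastructure"),
               "5\\.01\\.02.*BBB")

  # missing item column is named
  expect_error(assembleResponses(rawSurveyFrame(m[, -3]), reg,
                                 "infrastructure"), "3\\.01\\.14")
})

test_that("private-market assembly computes the composite row-wise", {
  reg <- loadRegistry()
  items <- indexItems(reg, "private_market")
  set.seed(4)
  N <- 10
  m <- matrix(rbinom(N * 25, 1, 0.6), N, 25,
              dimnames = list(sprintf("P%02d", 1:N),
                              items$item_id[!items$derived]))
  m[1, ] <- 1L
  raw <- rawSurveyFrame(m)
  freq <- data.frame(
    insp.freq.manufacturers = c(1, 2, 5, 3, NA, 1, 4, 2, 3, 5),
    insp.freq.retail = c(1, 3, 5, 3, 2, 4, 4, 1, 3, 5),
    insp.freq.dispensing = c(1, 2, 6, 3, 2, 6, 4, 6, 3, 0.5))
  raw <- cbind(raw, freq)
  for (variant in c("regular", "annual")) {
    rs <- assembleResponses(raw, reg, "private_market", variant)
    expect_equal(ncol(responseMatrix(rs)), 26L)
    got <- responseMatrix(rs)[, "inspections"]
    want <- mapply(bruteForceComposite, freq[[1]], freq[[2]], freq[[3]],
                   MoreArgs = list(variant = variant))
    expect_equal(unname(got), unname(want))
  }
  # the two variants disagree on this table
  rsR <- assembleResponses(raw, reg, "private_market", "regular")
  rsA <- assembleResponses(raw, reg, "private_market", "annual")
  expect_false(identical(responseMatrix(rsR)[, "inspections"],
                         responseMatrix(rsA)[, "inspections"]))
})

test_that("ResponseSet rejects empty rows/columns and duplicates", {
  m <- matrix(c(1L, 0L, 1L, NA, 1L, 0L, 0L, 1L, 1L), 3, 3,
              dimnames = list(c("AAA", "BBB", "CCC"), c("a", "b", "c")))
  expect_s4_class(ResponseSet(m), "ResponseSet")
  m2 <- m
  m2["BBB", ] <- NA_integer_   # columns keep observations in AAA/CCC
  expect_error(ResponseSet(m2), "BBB")
  m3 <- m
  m3[, "c"] <- NA_integer_
  expect_error(ResponseSet(m3), "c")
  m4 <- m
  rownames(m4) <- c("AAA", "AAA", "CCC")
  expect_error(ResponseSet(m4), "duplicate")
})

test_that("survey CSV round-trips with missing cells", {
  rs <- paperlikeScenario("public_quality", seed = 2)$responses
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeSurveyCSV(rs, tmp)
  raw <- readSurveyCSV(tmp)
  rs2 <- assembleResponses(raw, loadRegistry(), "public_quality")
  expect_equal(responseMatrix(rs2), responseMatrix(rs))
})
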