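# Courses used repeatedly: a stimulus that triples the signal at the last
# time point, against a flat reference.
risingCourses <- list("|" = c(1000, 1000, 1000),
                      "S1|" = c(1000, 1000, 3000))

test_that("a stimulus is significant when its increase clears k error SDs", {
  ds <- courseDataset(risingCourses)
  em <- ErrorModel(300, 0)
  # 2000 > 2.5 * sqrt(2 * 300^2) = 1060.7
  expect_identical(stimulusSignificant(ds, em, "P", "S1", 2.5), 1L)
  # one-sided: identical courses can never be significant
  ds2 <- courseDataset(list("|" = c(1000, 1000, 3000),
                            "S1|" = c(1000, 1000, 3000)))
  expect_identical(stimulusSignificant(ds2, em, "P", "S1", 2.5), 0L)
  # decreases do not count either
  ds3 <- courseDataset(list("|" = c(1000, 3000, 3000),
                            "S1|" = c(1000, 1000, 1000)))
  expect_identical(stimulusSignificant(ds3, em, "P", "S1", 0.5), 0L)
  expect_lte(stimulusKThreshold(ds3, em, "P", "S1"), 0)
  expect_error(stimulusSignificant(ds, em, "P", "S1", 0), "positive")
})

test_that("the analytic stimulus threshold matches direct evaluation", {
  ds <- courseDataset(risingCourses)
  em <- ErrorModel(300, 0)
  # max_t Delta/sd_Delta = 2000 / 424.264 = 4.714
  expect_equal(stimulusKThreshold(ds, em, "P", "S1"), 2000 / sqrt(180000),
               tolerance = 1e-12)
  expect_equal(stimulusKThreshold(ds, em, "P", "S1"), 4.7140452,
               tolerance = 1e-7)
})

test_that("inhibitor significance needs a drop below the stimulus course", {
  em <- ErrorModel(300, 0)
  # drop of 100 at t = 30: well under 2.5 * 424.26
  ds <- courseDataset(list("|" = c(1000, 1000),
                           "S1|" = c(1000, 3000),
                           "S1|K1i" = c(1000, 2900)),
                      timepoints = c(0, 30))
  expect_identical(inhibitorSignificant(ds, em, "P", "S1", "K1i", 2.5), 0L)
  expect_equal(inhibitorKThreshold(ds, em, "P", "S1", "K1i"),
               100 / sqrt(180000), tolerance = 1e-12)
  # a full block is significant
  ds2 <- courseDataset(list("|" = c(1000, 1000),
                            "S1|" = c(1000, 3000),
                            "S1|K1i" = c(1000, 1000)),
                       timepoints = c(0, 30))
  expect_identical(inhibitorSignificant(ds2, em, "P", "S1", "K1i", 2.5), 1L)
})

test_that("inhibitor assessment is a contract violation when the stimulus is silent", {
  em <- ErrorModel(300, 0)
  ds <- courseDataset(list("|" = c(1000, 1000),
                           "S1|" = c(1000, 1010),
                           "S1|K1i" = c(1000, 400)),
                      timepoints = c(0, 30))
  expect_error(inhibitorSignificant(ds, em, "P", "S1", "K1i", 2.5),
               "not significant")
})

test_that("tables on a mediated ground truth have the textbook cell pattern", {
  # S1 -> K1 -> P: the column for S1 is [1,1] at K1i and [1,0] at K2i;
  # a silent stimulus S2 gives an all-[0,0] column.
  em <- ErrorModel()
  eff <- 10 * em@technicalSD
  effects <- data.frame(stimulus = "S1", protein = "P1", effect = eff,
                        mediator = "K1")
  net <- new("SignalingNetwork", stimulusNodes = "S1",
             inhibitedNodes = "K1", measuredNodes = "P1",
             edges = data.frame(from = c("S1", "K1"), to = c("K1", "P1")))
  truth <- new("GroundTruth", network = net, basal = c(P1 = 1000),
               effects = effects, timepoints = c(0, 30, 180),
               errorModel = em, stimuli = c("S1", "S2"),
               inhibitors = c("K1i", "K2i"),
               inhibitorTargets = c(K1i = "K1", K2i = "K2"),
               seed = 5L)
  ds <- simulateDataset(truth, noise = FALSE)
  tb <- buildBooleanTable(ds, em, "P1", k = 2.5)
  expect_identical(tb@s, c(S1 = 1L, S2 = 0L))
  expect_identical(tb@v["K1i", "S1"], 1L)
  expect_identical(tb@v["K2i", "S1"], 0L)
  expect_identical(unname(tb@v[, "S2"]), c(0L, 0L))
  # an unreachable threshold empties the table
  tb2 <- buildBooleanTable(ds, em, "P1", k = 1e6)
  expect_true(all(tb2@s == 0L) && all(tb2@v == 0L))
})

test_that("flat data yield all-zero tables", {
  truth <- flatTruth(seed = 3)
  ds <- simulateDataset(truth, noise = FALSE)
  for (p in proteins(ds)) {
    tb <- buildBooleanTable(ds, ErrorModel(), p, k = 2.5)
    expect_true(all(tb@s == 0L) && all(tb@v == 0L))
  }
})

test_that("significance is monotone in k and matches the analytic threshold", {
  em <- ErrorModel()
  grid <- seq(0.5, 10, by = 0.5)
  for (seed in 1:10) {
    truth <- sampleGroundTruth(2, 2, 2, pDirect = 0.3, pMediated = 0.3,
                               seed = seed)
    ds <- simulateDataset(truth, noise = TRUE)
    for (p in proteins(ds)) for (i in stimulusIds(ds)) {
      sig <- stimulusSignificant(ds, em, p, i, grid)
      kmax <- stimulusKThreshold(ds, em, p, i)
      expect_identical(sig == 1L, grid < kmax)
      expect_true(all(diff(sig) <= 0))        # monotone: 1s before 0s
      below <- grid[grid < kmax]
      if (length(below)) for (j in inhibitorIds(ds)) {
        vsig <- inhibitorSignificant(ds, em, p, i, j, below)
        expect_identical(vsig == 1L,
                         below < inhibitorKThreshold(ds, em, p, i, j))
      }
    }
  }
})

test_that("table invariants are enforced by the class", {
  expect_error(new("BooleanTable", protein = "P",
                   s = c(S1 = 0L),
                   v = matrix(1L, 1, 1, dimnames = list("K1i", "S1")),
                   mediators = list(S1 = character(0))),
               "s = 0 implies v = 0")
})

test_that("thresholds serialize to JSON and tables to CSV", {
  truth <- sampleGroundTruth(2, 1, 2, pDirect = 0.4, pMediated = 0.3,
                             seed = 2)
  ds <- simulateDataset(truth, noise = TRUE)
  em <- ErrorModel()
  thr <- kThresholds(ds, em)
  expect_named(thr, proteins(ds))
  expect_equal(thr$P1$stimulus[["S1"]],
               stimulusKThreshold(ds, em, "P1", "S1"))
  dir <- withr::local_tempdir()
  jf <- file.path(dir, "thr.json")
  writeKThresholds(thr, jf)
  back <- jsonlite::read_json(jf)
  expect_equal(back$P1$stimulus$S1, thr$P1$stimulus[["S1"]],
               tolerance = 1e-12)
  tabs <- lapply(proteins(ds), function(p)
    buildBooleanTable(ds, em, p, 2.5))
  names(tabs) <- proteins(ds)
  paths <- writeBooleanTables(tabs, dir)
  expect_true(all(file.exists(paths)))
  got <- utils::read.csv(paths[["P1"]], row.names = 1,
                         colClasses = "character")
  expect_equal(unname(unlist(got["K1i", "S1"])),
               paste(tabs$P1@s[["S1"]], tabs$P1@v["K1i", "S1"], sep = ","))
})
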