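# A hand-wired InferredModel around the AKT-style topology, with explicit
# training values so the superposition formula can be checked by
# arithmetic. Conditions cover the reference, both stimuli, both
# inhibitors and the crossings used by prediction.
aktManualFit <- function(vals = list()) {
  stim <- c("IGF1", "TGFa"); inh <- c("MEKi", "PI3Ki")
  targets <- c(MEKi = "MEK12", PI3Ki = "PI3K")
  d <- function(a, b) c(a, b)             # courses over t = (0, 30)
  defaults <- list(
    "|" = d(300, 300), "|PI3Ki" = d(300, 300), "|MEKi" = d(300, 300),
    "TGFa|" = d(300, 800), "IGF1|" = d(300, 700),
    "TGFa|PI3Ki" = d(300, 800), "IGF1|PI3Ki" = d(300, 700),
    "TGFa|MEKi" = d(300, 800), "IGF1|MEKi" = d(300, 700))
  defaults[names(vals)] <- vals
  ds <- courseDataset(defaults, timepoints = c(0, 30), proteins = "AKT",
                      stimulusIds = stim, inhibitorIds = inh,
                      inhibitorTargets = targets)
  tb <- manualTable("AKT", stim, inh,
                    sOn = c("IGF1", "TGFa"),
                    vOn = list(IGF1 = "PI3Ki", TGFa = "PI3Ki"))
  pathsList <- list(AKT = tableToLinks(tb, targets))
  merged <- mergeAndPrune(pathsList, list(AKT = tb), targets)
  fit <- new("InferredModel", network = merged$network,
             tables = merged$tables, paths = pathsList,
             rankedLinks = data.frame(path = character(0),
                                      k_upper = numeric(0)),
             k = 2.5, errorModel = ErrorModel())
  list(ds = ds, fit = fit)
}

test_that("two stimuli sharing one mediating inhibitor reduce to the textbook sum", {
  z <- aktManualFit(list("TGFa|PI3Ki" = c(300, 800),
                         "IGF1|PI3Ki" = c(300, 700),
                         "|PI3Ki" = c(300, 300)))
  rec <- predictCondition(z$ds, z$fit, "AKT",
                          stimuli = c("TGFa", "IGF1"),
                          inhibitors = c("MEKi", "PI3Ki"), time = 30)
  # X(TGFa,PI3Ki) + X(IGF1,PI3Ki) - X(0,PI3Ki) = 800 + 700 - 300
  expect_equal(rec$predicted, 1200, tolerance = 1e-12)
  expect_setequal(rec$active_stimuli, c("TGFa", "IGF1"))
  expect_identical(rec$mediators$TGFa, "PI3Ki")
  # the unlinked inhibitor MEKi plays no role
  rec2 <- predictCondition(z$ds, z$fit, "AKT",
                           stimuli = c("TGFa", "IGF1"),
                           inhibitors = "PI3Ki", time = 30)
  expect_equal(rec2$predicted, rec$predicted, tolerance = 1e-12)
})

test_that("single-stimulus predictions collapse to the training condition", {
  z <- aktManualFit()
  # one active stimulus with its mediator applied: exactly X(t|i,j)
  r1 <- predictCondition(z$ds, z$fit, "AKT", stimuli = "TGFa",
                         inhibitors = "PI3Ki", time = 30)
  expect_equal(r1$predicted,
               levelAt(z$ds, "AKT", "TGFa", "PI3Ki", 30),
               tolerance = 1e-12)
  # one active stimulus, no inhibitors: exactly X(t|i,0)
  r2 <- predictCondition(z$ds, z$fit, "AKT", stimuli = "IGF1", time = 30)
  expect_equal(r2$predicted,
               levelAt(z$ds, "AKT", "IGF1", character(0), 30),
               tolerance = 1e-12)
})

test_that("prediction is invariant to treatment ordering and clamps at zero", {
  z <- aktManualFit()
  a <- predictCondition(z$ds, z$fit, "AKT", c("TGFa", "IGF1"),
                        c("MEKi", "PI3Ki"), 30)
  b <- predictCondition(z$ds, z$fit, "AKT", c("IGF1", "TGFa"),
                        c("PI3Ki", "MEKi"), 30)
  expect_identical(a$predicted, b$predicted)
  # push the sum negative: both mediated conditions far below reference
  z2 <- aktManualFit(list("TGFa|PI3Ki" = c(300, 10),
                          "IGF1|PI3Ki" = c(300, 10),
                          "|PI3Ki" = c(300, 900)))
  r <- predictCondition(z2$ds, z2$fit, "AKT", c("TGFa", "IGF1"),
                        "PI3Ki", 30)
  expect_identical(r$predicted, 0)
})

test_that("without active stimuli the prediction is the reference, and t = 0 is basal", {
  z <- aktManualFit()
  r <- predictCondition(z$ds, z$fit, "AKT", character(0), "PI3Ki", 30)
  expect_equal(r$predicted, levelAt(z$ds, "AKT", character(0), "PI3Ki", 30))
  r0 <- predictCondition(z$ds, z$fit, "AKT", c("TGFa", "IGF1"),
                         "PI3Ki", 0)
  expect_equal(r0$predicted, r0$reference_used)
})

test_that("non-affecting stimuli are averaged into the reference", {
  # S2 does not act on P: the reference becomes the mean of the untreated
  # level and the S2-alone level (both estimate the same baseline).
  stim <- c("S1", "S2"); inh <- "K1i"
  ds <- courseDataset(list(
    "|" = c(500, 520), "S1|" = c(500, 2500), "S2|" = c(500, 480),
    "|K1i" = c(500, 530), "S1|K1i" = c(500, 2500),
    "S2|K1i" = c(500, 470)),
    timepoints = c(0, 30), proteins = "P",
    stimulusIds = stim, inhibitorIds = inh,
    inhibitorTargets = c(K1i = "K1"))
  tb <- manualTable("P", stim, inh, sOn = "S1")
  fit <- new("InferredModel",
             network = mergeAndPrune(list(P = tableToLinks(tb, c(K1i = "K1"))),
                                     list(P = tb), c(K1i = "K1"))$network,
             tables = list(P = tb), paths = list(P = tableToLinks(tb, c(K1i = "K1"))),
             rankedLinks = data.frame(path = character(0), k_upper = numeric(0)),
             k = 2.5, errorModel = ErrorModel())
  expect_equal(referenceLevel(ds, booleanTables(fit), "P", character(0), 30),
               mean(c(520, 480)))
  # with no applied (linked) inhibitor the same averaging enters Eq.-style
  # subtraction, so a lone active stimulus still collapses exactly
  r <- predictCondition(ds, fit, "P", "S1", character(0), 30)
  expect_equal(r$predicted, 2500, tolerance = 1e-12)
  # prediction for {S1, S2}: S2 inactive, contributes nothing
  r2 <- predictCondition(ds, fit, "P", c("S1", "S2"), character(0), 30)
  expect_equal(r2$predicted, mean(c(520, 480)) + (2500 - mean(c(520, 480))),
               tolerance = 1e-12)
})

test_that("noise-free additive truth is predicted exactly", {
  truth <- sampleGroundTruth(seed = 29)
  ds <- simulateDataset(truth, noise = FALSE)
  fit <- reconstructNetwork(ds, ErrorModel(), k = 2.5)
  tasks <- defaultTestTasks(truth)
  tt <- simulateTestTruth(truth, tasks)
  rec <- predictBatch(ds, fit, tasks)
  expect_equal(nrow(rec), nrow(tasks))
  relErr <- abs(rec$predicted - tt$measured) / pmax(abs(tt$measured), 1)
  expect_lt(max(relErr), 1e-9)
})

test_that("batch prediction preserves order, handles empties, and names bad tasks", {
  truth <- sampleGroundTruth(seed = 29)
  ds <- simulateDataset(truth, noise = FALSE)
  fit <- reconstructNetwork(ds, ErrorModel(), k = 2.5)
  empty <- predictBatch(ds, fit, data.frame(protein = character(0),
                                            stimuli = character(0),
                                            inhibitors = character(0),
                                            time_min = numeric(0)))
  expect_identical(nrow(empty), 0L)
  tasks <- data.frame(protein = c("P2", "P1"), stimuli = c("S1", "S2"),
                      inhibitors = c("", "K1i"), time_min = 30)
  rec <- predictBatch(ds, fit, tasks)
  expect_identical(rec$protein, c("P2", "P1"))
  bad <- data.frame(protein = "P1", stimuli = "S1", inhibitors = "",
                    time_min = 999)
  expect_error(predictBatch(ds, fit, bad), "task 1.*t = 999")
})

test_that("subnetwork isolation keeps only routing nodes", {
  z <- aktManualFit()
  # AKT's own fit has IGF1/TGFa -> PI3K -> AKT; MEKi routes nowhere
  sub <- isolateSubnetwork(network(z$fit), "AKT", c("TGFa", "IGF1"),
                           c("MEKi", "PI3Ki"),
                           c(MEKi = "MEK12", PI3Ki = "PI3K"))
  expect_setequal(sub$nodes, c("AKT", "TGFa", "IGF1", "PI3K"))
  expect_false("MEK12" %in% sub$nodes)
  expect_setequal(paste(sub$edges$from, sub$edges$to, sep = "->"),
                  c("TGFa->PI3K", "IGF1->PI3K", "PI3K->AKT"))
  # a protein with no links isolates to itself
  net2 <- new("SignalingNetwork", stimulusNodes = "S1",
              inhibitedNodes = character(0), measuredNodes = c("P1", "P2"),
              edges = data.frame(from = "S1", to = "P1"))
  sub2 <- isolateSubnetwork(net2, "P2", "S1", character(0), character(0))
  expect_identical(sub2$nodes, "P2")
  expect_identical(nrow(sub2$edges), 0L)
  # empty stimulus set: only the protein and linked J-nodes remain
  sub3 <- isolateSubnetwork(network(z$fit), "AKT", character(0),
                            c("MEKi", "PI3Ki"),
                            c(MEKi = "MEK12", PI3Ki = "PI3K"))
  expect_identical(sub3$nodes, "AKT")
  expect_error(isolateSubnetwork(network(z$fit), "NOPE", "TGFa",
                                 character(0), character(0)),
               "unknown protein")
})
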