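test_that("identical specs give bit-identical subjects and cohorts", {
  s1 <- simulateSubject(tinySpec(seed = 7L), 2L, 1L)
  s2 <- simulateSubject(tinySpec(seed = 7L), 2L, 1L)
  expect_identical(epochsData(s1$cognitive), epochsData(s2$cognitive))
  expect_identical(epochsData(s1$mi), epochsData(s2$mi))
  s3 <- simulateSubject(tinySpec(seed = 8L), 2L, 1L)
  expect_false(identical(epochsData(s3$cognitive), epochsData(s1$cognitive)))
})

test_that("subject datasets have the designed shape and annotations", {
  spec <- tinySpec()
  sub <- simulateSubject(spec, 1L, 3L)
  expect_identical(dim(epochsData(sub$cognitive)), c(12L, 19L, 1200L))
  expect_identical(dim(epochsData(sub$mi)), c(24L, 12L, 6000L))
  expect_identical(channelNames(sub$cognitive), COGNITIVE_CHANNELS)
  expect_identical(channelNames(sub$mi), MI_CHANNELS)
  annCog <- annotations(sub$cognitive)
  expect_true(all(table(annCog$action) == spec$cognitiveTrialsPerAction))
  annMi <- annotations(sub$mi)
  expect_true(all(table(annMi$action, annMi$hand) ==
                    spec$miTrialsPerAction / 2))
  expect_identical(sub$trueStrongAction, 3L)
})

test_that("cohort strong-action assignment is seeded and covers actions", {
  spec <- simulationSpec(nSubjects = 10L, cognitiveTrialsPerAction = 2L,
                         miTrialsPerAction = 2L, seed = 3L)
  # assignment only (cheap): reach through the same seeded stream
  coh <- simulateCohort(simulationSpec(nSubjects = 10L,
                                       cognitiveTrialsPerAction = 1L,
                                       miTrialsPerAction = 2L, seed = 3L))
  strongs <- vapply(coh, `[[`, 0L, "trueStrongAction")
  expect_length(coh, 10L)
  expect_setequal(unique(strongs), 1:3)
  expect_error(simulateCohort(simulationSpec(nSubjects = 1L)),
               "at least 2 subjects")
})

test_that("spec invariants are enforced", {
  expect_error(simulationSpec(couplingStrong = 0.2, couplingWeak = 0.5),
               "couplingStrong >= couplingWeak")
  expect_error(simulationSpec(erdDepthStrong = 1.2), "\\[0, 1\\]")
  expect_error(simulationSpec(miTrialsPerAction = 7), "even")
})

test_that("stronger coupling raises inter-channel correlation of cognitive trials", {
  spec <- simulationSpec(nSubjects = 2L, cognitiveTrialsPerAction = 10L,
                         miTrialsPerAction = 2L, couplingStrong = 0.8,
                         couplingWeak = 0.3, seed = 11L)
  sub <- simulateSubject(spec, 1L, 1L)
  prepped <- preprocessCognitive(sub$cognitive)
  ann <- annotations(prepped)
  meanPcc <- function(idx) {
    mean(vapply(idx, function(i) {
      A <- pccAdjacency(downsampleAverage(trialMatrix(prepped, i)))
      mean(A[row(A) != col(A)])
    }, 0))
  }
  pccStrong <- meanPcc(which(ann$action == 1))
  pccWeak <- meanPcc(which(ann$action != 1))
  expect_gt(pccStrong, pccWeak)
})

test_that("null effects make strong and weak trials exchangeable", {
  spec <- simulationSpec(nSubjects = 2L, cognitiveTrialsPerAction = 12L,
                         miTrialsPerAction = 2L, couplingStrong = 0.5,
                         couplingWeak = 0.5, bandpowerShift = 0,
                         erdDepthStrong = 0.3, erdDepthWeak = 0.3,
                         seed = 13L)
  sub <- simulateSubject(spec, 1L, 2L)
  d <- epochsData(sub$cognitive)
  ann <- annotations(sub$cognitive)
  vStrong <- mean(d[ann$action == 2, , ]^2)
  vWeak <- mean(d[ann$action != 2, , ]^2)
  # identical generative parameters: per-trial power matches closely
  expect_lt(abs(vStrong - vWeak) / vWeak, 0.05)
})

test_that("coupling-gap monotonicity holds in expectation over seeds", {
  gapFor <- function(cs, cw, seed) {
    spec <- simulationSpec(nSubjects = 2L, cognitiveTrialsPerAction = 4L,
                           miTrialsPerAction = 2L, couplingStrong = cs,
                           couplingWeak = cw, seed = seed)
    sub <- simulateSubject(spec, 1L, 1L)
    prepped <- preprocessCognitive(sub$cognitive)
    ann <- annotations(prepped)
    m <- vapply(seq_len(nTrials(prepped)), function(i) {
      A <- pccAdjacency(downsampleAverage(trialMatrix(prepped, i)))
      mean(A[row(A) != col(A)])
    }, 0)
    mean(m[ann$action == 1]) - mean(m[ann$action != 1])
  }
  seeds <- 1:20
  gapSmall <- mean(vapply(seeds, function(s) gapFor(0.5, 0.4, s), 0))
  gapLarge <- mean(vapply(seeds, function(s) gapFor(0.9, 0.2, s), 0))
  expect_gt(gapLarge, gapSmall)
})
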