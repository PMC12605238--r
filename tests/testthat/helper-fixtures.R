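# Shared small fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Reduced-scale cohort: full channel counts and epoch lengths, fewer
# trials, so every pipeline stage runs in seconds.
tinySpec <- function(seed = 42L, ...) {
  simulationSpec(nSubjects = 3L, cognitiveTrialsPerAction = 4L,
                 miTrialsPerAction = 8L, seed = seed, ...)
}

tinyCohort <- function() {
  if (is.null(.fixtures$cohort)) .fixtures$cohort <- simulateCohort(tinySpec())
  .fixtures$cohort
}

tinyPreppedCognitive <- function() {
  if (is.null(.fixtures$prepped)) {
    .fixtures$prepped <- lapply(tinyCohort(),
                                function(s) preprocessCognitive(s$cognitive))
  }
  .fixtures$prepped
}

# A CSP model fitted on subjects 2 and 3 of the tiny cohort (subject 1
# held out), using the simulated truth as the class split.
tinyCsp <- function() {
  if (is.null(.fixtures$csp)) {
    coh <- tinyCohort()
    prepped <- tinyPreppedCognitive()
    strong <- list()
    weak <- list()
    for (k in 2:3) {
      lab <- annotations(prepped[[k]])$action == coh[[k]]$trueStrongAction
      for (i in seq_len(nTrials(prepped[[k]]))) {
        m <- trialMatrix(prepped[[k]], i)
        if (lab[i]) strong <- c(strong, list(m)) else weak <- c(weak, list(m))
      }
    }
    .fixtures$csp <- fitCsp(strong, weak)
  }
  .fixtures$csp
}

# Random symmetric adjacency with entries in [0, 1] and unit diagonal.
randomAdjacency <- function(S) {
  M <- matrix(runif(S * S), S)
  A <- (M + t(M)) / 2
  diag(A) <- 1
  A
}

# Graph triples that are linearly separable by class: "strong" trials
# get uniformly higher edge weights and node features.
separableGraphs <- function(n, seed = 1L, subject = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    strong <- i %% 2 == 1
    shift <- if (strong) 0.8 else -0.8
    meta <- list(subject = subject, action = if (strong) 1 else 2,
                 label = if (strong) "strong" else "weak")
    base <- if (strong) 0.7 else 0.3
    mkA <- function() {
      M <- matrix(runif(19 * 19, base - 0.2, base + 0.2), 19)
      A <- (M + t(M)) / 2
      diag(A) <- 1
      pmin(pmax(A, 0), 1)
    }
    list(time = DomainGraph(matrix(rnorm(19 * 40, shift), 19, 40), mkA(),
                            "time", meta),
         frequency = DomainGraph(matrix(rnorm(19 * 4, shift), 19, 4), mkA(),
                                 "frequency", meta),
         spatial = DomainGraph(matrix(rnorm(19, shift), 19, 1), mkA(),
                               "spatial", meta))
  })
}

graphLabels <- function(graphs) {
  vapply(graphs, function(g) g$time@annotation$label, "")
}
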