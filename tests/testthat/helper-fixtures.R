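# Shared fixtures, all generated in code under fixed seeds.

# random band-limited real spherical signal (coefficients + grid samples)
randomBandLimited <- function(B, seed) {
  set.seed(seed)
  fh <- randomRealCoefficients(B)
  list(fh = fh, f = shtInverse(fh))
}

# brute-force C-index oracle: plain enumeration of all ordered pairs under
# Harrell's comparability rules, independent of the package implementation
bruteForceCIndex <- function(h, time, event) {
  num <- 0; den <- 0
  n <- length(h)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    comparable <- (event[i] == 1 && time[i] < time[j]) ||
      (event[i] == 1 && event[j] == 0 && time[i] == time[j])
    if (!comparable) next
    den <- den + 1
    if (h[i] > h[j]) num <- num + 1
    else if (h[i] == h[j]) num <- num + 0.5
  }
  num / den
}

# random censored cohort for property tests
randomCohort <- function(n, seed, censorFraction = 0.3, tieProb = 0) {
  set.seed(seed)
  time <- round(rexp(n, 0.1), if (tieProb > 0) 0 else 4) + 0.5
  event <- as.integer(runif(n) > censorFraction)
  h <- rnorm(n)
  list(time = time, event = event, h = h,
       cohort = survivalCohort(time, event))
}

# a small shared phantom set, built once per test run
phantomFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantomCohortSpec(nSubjects = 5, seed = 42)
      cache <<- list(spec = spec,
                     subjects = lapply(1:5, function(i) generateMask(spec, i)))
    }
    cache
  }
})

# tiny network configuration for fast structural tests
tinyConfig <- function() networkConfig(bandwidth = 8, inputConfig = "sphcnn1",
                                       c1 = 2, c2 = 3, l1 = 4, l2 = 2)

halfVoxelDiagonal <- function(spacing = c(1, 1, 1)) sqrt(sum(spacing^2)) / 2
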