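test_that("scored-nuclei tables round-trip through write and read losslessly", {
  pop <- genNucleiPopulation(25, ploidy = "4C", pAssoc = 0.4, pCohesion = 0.5,
                             pElongation = 0.3, pOutloop = 0.2, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeScoredNuclei(pop, path, comments = c("synthetic fixture", "seed=11"))
  back <- readScoredNuclei(path)
  expect_equal(as.data.frame(observations(back)),
               as.data.frame(observations(pop)))
})

test_that("malformed tables are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "nucleus_id\tploidy\ttissue\tprobe_id\thomolog_index\tsignal_count\tpositions\tflags",
    "n1\t2C\tleaf\tA\t1\t1\t\t",
    "n1\t2C\tleaf\tA\t1\t2\t\t",     # duplicate triple
    "n2\t3C\tleaf\tA\t1\t1\t\t",     # unknown ploidy
    "n3\t2C\tleaf\tA\t1\t0\t\t"      # zero signals
  ), path)
  err <- tryCatch(readScoredNuclei(path), error = conditionMessage)
  expect_match(err, "line 3: duplicate")
  expect_match(err, "line 4: unknown ploidy")
  expect_match(err, "line 5: signal_count")
})

test_that("an empty table reads as an empty collection", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# only comments", path)
  expect_identical(nrow(observations(readScoredNuclei(path))), 0L)
})

test_that("association frequency reproduces the worked-example fixtures", {
  # 27 of 200 2C nuclei flagged -> the reported 13.5%
  f <- associationFrequency(assocFixture(27, 200), "A", "B")
  expect_identical(successes(f), 27L)
  expect_identical(trials(f), 200L)
  expect_equal(percent(f), 13.5)
  # 20 of 90 4C nuclei -> displays as 22.2%
  f4 <- associationFrequency(assocFixture(20, 90, ploidy = "4C"), "A", "B")
  expect_equal(displayPercent(percent(f4)), 22.2)
  # none flagged -> 0%
  expect_equal(percent(associationFrequency(assocFixture(0, 50), "A", "B")), 0)
  expect_error(associationFrequency(assocFixture(5, 10), "A", "Z"),
               "both probes")
})

test_that("flag-based and position-based association scoring agree when flags derive from the same threshold", {
  cfg <- defaultRSDConfig("trans")
  pop <- genNucleiPopulation(300, pAssoc = 0.2, relation = "trans",
                             config = cfg, seed = 23)
  byFlags <- associationFrequency(pop, "probeA", "probeB")
  byPos <- associationFrequency(pop, "probeA", "probeB",
                                threshold = 2 * signalRadius(cfg))
  expect_identical(successes(byFlags), successes(byPos))
  expect_identical(trials(byFlags), trials(byPos))
})

test_that("all frequency metrics are invariant under row permutation", {
  pop <- genNucleiPopulation(60, ploidy = "4C", pAssoc = 0.3, pCohesion = 0.4,
                             pElongation = 0.2, pOutloop = 0.1, seed = 31)
  df <- as.data.frame(observations(pop))
  set.seed(1)
  shuf <- ScoredNuclei(df[sample(nrow(df)), ])
  for (getter in list(
    function(x) associationFrequency(x, "probeA", "probeB"),
    function(x) elongationFrequency(x, "probeA"),
    function(x) cohesionFrequency(x, "probeA"),
    function(x) outloopFrequency(x, "probeA")
  )) {
    a <- getter(pop); b <- getter(shuf)
    expect_identical(successes(a), successes(b))
    expect_identical(trials(a), trials(b))
  }
})

test_that("elongation uses the ploidy-specific signal-number threshold", {
  mk <- function(counts, ploidy) {
    n <- length(counts)
    ScoredNuclei(data.frame(
      nucleus_id = sprintf("n%03d", seq_len(n)), ploidy = ploidy,
      tissue = "leaf", probe_id = "P", homolog_index = 1L,
      signal_count = counts, positions = NA_character_,
      flags = NA_character_))
  }
  # 48 elongated of 200 -> the reported 24.0% in 2C
  f <- elongationFrequency(mk(c(rep(3L, 48), rep(2L, 152)), "2C"), "P")
  expect_equal(percent(f), 24)
  expect_identical(trials(f), 200L)
  # exactly two signals in 2C is the boundary: not elongated
  expect_identical(successes(elongationFrequency(mk(c(2L, 2L), "2C"), "P")), 0L)
  # 4C threshold is four signals
  expect_identical(successes(elongationFrequency(mk(c(4L, 5L), "4C"), "P")), 1L)
  # hand count on an exhaustive small fixture
  counts <- c(1L, 2L, 3L, 4L, 5L)
  f2 <- elongationFrequency(mk(counts, "2C"), "P")
  expect_identical(successes(f2), sum(counts > 2L))
  mixed <- ScoredNuclei(rbind(
    as.data.frame(observations(mk(c(2L, 3L), "2C"))),
    within(as.data.frame(observations(mk(c(5L, 4L), "4C"))),
           nucleus_id <- paste0(nucleus_id, "x"))))
  expect_error(elongationFrequency(mixed, "P"), "ambiguous ploidy")
  expect_equal(percent(elongationFrequency(mixed, "P", ploidy = "2C")), 50)
})

test_that("cohesion counts fused homologs in replicated nuclei only", {
  mk <- function(counts, ploidy = "4C") {
    n <- length(counts)
    ScoredNuclei(data.frame(
      nucleus_id = sprintf("n%03d", rep(seq_len(ceiling(n / 2)), each = 2))[1:n],
      ploidy = ploidy, tissue = "leaf", probe_id = "T20O10",
      homolog_index = rep(1:2, length.out = n),
      signal_count = counts, positions = NA_character_,
      flags = NA_character_))
  }
  # 50 fused of 86 homologs -> displays as the reported 58.1%
  f <- cohesionFrequency(mk(c(rep(1L, 50), rep(2L, 36))), "T20O10")
  expect_identical(trials(f), 86L)
  expect_equal(displayPercent(percent(f)), 58.1)
  expect_equal(percent(cohesionFrequency(mk(rep(1L, 10)), "T20O10")), 100)
  expect_error(cohesionFrequency(mk(c(1L, 1L), ploidy = "2C"), "T20O10"),
               "cohesion undefined")
  # brute-force tally on a random fixture
  set.seed(12)
  counts <- sample(1:2, 40, replace = TRUE)
  expect_identical(successes(cohesionFrequency(mk(counts), "T20O10")),
                   sum(counts == 1L))
})

test_that("separation requires adjacency and counts homologs or chromatids", {
  segs <- genSegmentAnnotation(
    c(Chr3 = 1e6),
    data.frame(chrom = "Chr3", start = c(0, 80000, 500000),
               length = c(80000, 80000, 10000),
               id = c("F16M2", "T20O10", "FARAWAY")))
  mk <- function(nSep, n, ploidy = "2C") {
    ids <- sprintf("n%03d", seq_len(n))
    flags <- c(rep("separated_from_adjacent", nSep), rep(NA_character_, n - nSep))
    ScoredNuclei(rbind(
      data.frame(nucleus_id = ids, ploidy = ploidy, tissue = "leaf",
                 probe_id = "F16M2", homolog_index = 1L, signal_count = 1L,
                 positions = NA_character_, flags = flags),
      data.frame(nucleus_id = ids, ploidy = ploidy, tissue = "leaf",
                 probe_id = "T20O10", homolog_index = 1L, signal_count = 1L,
                 positions = NA_character_, flags = NA_character_)))
  }
  # 23 separated of 40 homologs -> the reported 57.5%
  f <- separationFrequency(mk(23, 40), "F16M2", "T20O10", segs)
  expect_equal(percent(f), 57.5)
  expect_equal(percent(separationFrequency(mk(0, 20), "F16M2", "T20O10", segs)), 0)
  # 4C: per-chromatid units double both k and n
  f4 <- separationFrequency(mk(7, 20, ploidy = "4C"), "F16M2", "T20O10", segs)
  expect_identical(trials(f4), 40L)
  expect_identical(successes(f4), 14L)
  expect_error(separationFrequency(mk(1, 5), "F16M2", "FARAWAY", segs),
               "not adjacent")
  expect_error(separationFrequency(mk(1, 5), "F16M2", "MISSING", segs),
               "annotation")
})

test_that("out-looping is the per-nucleus rate of the outside_CT flag", {
  n <- 150
  flags <- c(rep("outside_CT", 2), rep(NA_character_, n - 2))
  pop <- ScoredNuclei(data.frame(
    nucleus_id = sprintf("n%03d", seq_len(n)), ploidy = "2C", tissue = "leaf",
    probe_id = "F1M20", homolog_index = 1L, signal_count = 1L,
    positions = NA_character_, flags = flags))
  f <- outloopFrequency(pop, "F1M20", territoryProbe = "CT1top")
  expect_identical(successes(f), 2L)
  expect_equal(displayPercent(percent(f)), 1.3)
  allf <- pop
  allf@observations$flags <- "outside_CT"
  expect_equal(percent(outloopFrequency(allf, "F1M20")), 100)
  noflag <- pop
  noflag@observations$flags <- NA_character_
  expect_error(outloopFrequency(noflag, "F1M20"), "unscorable")
})

test_that("generator ground truth is recovered within the binomial CI at n = 500", {
  # each scored metric should sit inside the exact 95% CI of its generating
  # probability; aggregated over 5 seeds x 4 metrics, at most one borderline
  # miss is statistically plausible
  cfg <- RSDConfig(4, 2.5, 0.01, 1.5)
  hits <- 0L
  for (seed in 1:5) {
    pop <- genNucleiPopulation(500, ploidy = "4C", pAssoc = 0.15,
                               pCohesion = 0.6, pElongation = 0.25,
                               pOutloop = 0.1, config = cfg, seed = seed)
    fa <- associationFrequency(pop, "probeA", "probeB")
    fc <- cohesionFrequency(pop, "probeA")
    fe <- elongationFrequency(pop, "probeA")
    fo <- outloopFrequency(pop, "probeA")
    hits <- hits +
      ciContains(successes(fa), trials(fa), 0.15) +
      ciContains(successes(fc), trials(fc), 0.6) +
      ciContains(successes(fe), trials(fe), 0.25) +
      ciContains(successes(fo), trials(fo), 0.1)
  }
  expect_gte(hits, 19L)
})
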