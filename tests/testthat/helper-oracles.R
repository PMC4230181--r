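# Independent oracles and small fixture builders used across the suite.

# Two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, using choose() (independent of the dhyper-based implementation).
enumFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
  p0 <- prob[support == tab[1, 1]]
  min(1, sum(prob[prob <= p0 * (1 + 1e-7)]))
}

# Duplicate of the package's uniform-in-ellipse rejection sampler (bounding
# rectangle, chunks of 2*need + 8 draws) for the sampler-equivalence oracle.
oracleRunifEllipse <- function(n, a, b) {
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  while (got < n) {
    m <- 2L * (n - got) + 8L
    x <- runif(m, -a, a)
    y <- runif(m, -b, b)
    keep <- which((x / a)^2 + (y / b)^2 <= 1)
    take <- keep[seq_len(min(length(keep), n - got))]
    if (length(take)) {
      out[(got + 1L):(got + length(take)), ] <- cbind(x[take], y[take])
      got <- got + length(take)
    }
  }
  out
}

# Closed-form CDF of the distance between two uniform points in a unit-radius
# circle (classical result; independent of the package's grid integration).
circleDistCdf <- function(t) {
  if (t <= 0) return(0)
  if (t >= 2) return(1)
  x <- t / 2
  1 + (2 / pi) * ((t^2 - 1) * acos(x) - x * (1 + t^2 / 2) * sqrt(1 - x^2))
}

# Build a flag-based scored-nuclei fixture in which exactly k of n nuclei
# carry a mutual association flag for two probes.
assocFixture <- function(k, n, ploidy = "2C",
                         probes = c("A", "B")) {
  flagsA <- c(rep(paste0("associated_with:", probes[2]), k),
              rep(NA_character_, n - k))
  flagsB <- c(rep(paste0("associated_with:", probes[1]), k),
              rep(NA_character_, n - k))
  ids <- sprintf("n%04d", seq_len(n))
  ScoredNuclei(rbind(
    data.frame(nucleus_id = ids, ploidy = ploidy, tissue = "leaf",
               probe_id = probes[1], homolog_index = 1L, signal_count = 1L,
               positions = NA_character_, flags = flagsA),
    data.frame(nucleus_id = ids, ploidy = ploidy, tissue = "leaf",
               probe_id = probes[2], homolog_index = 1L, signal_count = 1L,
               positions = NA_character_, flags = flagsB)
  ))
}

# Exact binomial 95% CI containment of a true probability.
ciContains <- function(k, n, p) {
  ci <- binom.test(k, n)$conf.int
  p >= ci[1] && p <= ci[2]
}
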