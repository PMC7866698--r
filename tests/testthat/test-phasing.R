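# Population-based phasing (haplotype-copying Viterbi), trio phasing,
# and concordance metrics.

# independent scorer for a copying-pair path (shared convention with the
# decoder: uniform initial prior over pairs dropped)
scorePath <- hapdose:::scorePairPath

bruteForcePair <- function(haps, g, pos, rho, lambda) {
  H <- nrow(haps); S <- length(g)
  combos <- expand.grid(rep(list(seq_len(H * H)), S))
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    k <- as.integer(combos[r, ])
    path <- cbind((k - 1) %/% H + 1, (k - 1) %% H + 1)
    lp <- scorePath(haps, g, pos, rho, lambda, path)
    if (lp > best) best <- lp
  }
  best
}

test_that("a fully homozygous parent is phased trivially with any panel", {
  panel <- toyPanel(nSamples = 2, nSites = 5)
  st <- sites(panel)
  gt <- toyGenotypes(st, a = c(0, 1, 0, 1, 0), b = c(0, 1, 0, 1, 0))
  ph <- phaseWithPanel(gt, panel)
  expect_identical(ph@hap1, c(0L, 1L, 0L, 1L, 0L))
  expect_identical(ph@hap2, ph@hap1)
})

test_that("the true pair is recovered when it sits in the panel", {
  set.seed(31)
  n <- 20
  st <- toySites(n)
  h1 <- rbinom(n, 1, 0.5); h2 <- rbinom(n, 1, 0.5)
  noise <- replicate(2, rbinom(n, 1, 0.5))
  panel <- PhasedPanel(st, rbind(h1, noise[, 1], h2, noise[, 2]))
  gt <- toyGenotypes(st, a = pmin(h1, h2), b = pmax(h1, h2))
  ph <- phaseWithPanel(gt, panel, mismatchRate = 0.001)
  # oracle: exhaustive scan over ordered panel-haplotype pairs, no recomb
  haps <- haplotypes(panel)
  g <- h1 + h2
  scores <- outer(1:4, 1:4, Vectorize(function(x, y) {
    sum(ifelse(is.na(g), 0,
               abs(haps[x, ] + haps[y, ] - g) * log(0.001) +
                 (2 - abs(haps[x, ] + haps[y, ] - g)) * log(0.999)))
  }))
  expect_equal(max(scores), scores[1, 3])  # the true (h1, h2) pair wins
  het <- which(g == 1)
  expect_true(all(ph@hap1[het] == h1[het]) || all(ph@hap1[het] == h2[het]))
  # genotype consistency is a hard constraint
  expect_identical(ph@hap1 + ph@hap2, g)
})

test_that("Viterbi pair decoding equals exhaustive maximization (property)", {
  set.seed(32)
  for (rep in 1:12) {
    H <- sample(2:4, 1); S <- sample(2:4, 1)
    haps <- matrix(rbinom(H * S, 1, 0.5), H, S)
    st <- toySites(S)
    pos <- st$pos
    g <- rbinom(S, 2, 0.5)
    if (rep %% 3 == 0) g[sample(S, 1)] <- NA
    rho <- 10^runif(1, -5, -3)
    res <- hapdose:::diploid_viterbi_cpp(haps, as.integer(g),
                                         as.numeric(pos), rho, 0.01)
    expect_equal(res$logLik, bruteForcePair(haps, g, pos, rho, 0.01),
                 tolerance = 1e-9)
    expect_equal(scorePath(haps, g, pos, rho, 0.01, res$path), res$logLik,
                 tolerance = 1e-9)
  }
})

test_that("phasing output is genotype-consistent at every site (property)", {
  set.seed(33)
  cfg <- simConfig(nPanelSamples = 40, nSites = 30, nFfSites = 0)
  panel <- simulatePanel(cfg, seed = 331)
  for (i in 1:5) {
    fam <- simulateFamily(panel, cfg, seed = 400 + i)
    ph <- phaseWithPanel(fam$fatherGt, panel)
    g <- fam$fatherGt$allele_a + fam$fatherGt$allele_b
    expect_identical(ph@hap1 + ph@hap2, g)
  }
})

test_that("trio phasing applies Mendelian transmission rules", {
  st <- toySites(5)
  # site 1: both het, child hom-alt -> both transmit 1
  # site 2: father hom-ref, mother het, child het -> mother transmitted 1
  # site 3: both het, child het -> ambiguous, unphased
  # site 4: inconsistent (parents hom-ref, child hom-alt) -> excluded
  # site 5: father het, mother hom-alt, child het -> father transmitted 0
  fa <- toyGenotypes(st, a = c(0, 0, 0, 0, 0), b = c(1, 0, 1, 0, 1))
  mo <- toyGenotypes(st, a = c(0, 0, 0, 0, 1), b = c(1, 1, 1, 0, 1))
  ch <- toyGenotypes(st, a = c(1, 0, 0, 1, 0), b = c(1, 1, 1, 1, 1))
  res <- phaseTrio(fa, mo, ch)
  expect_identical(res$father@hap1[1], 1L)
  expect_identical(res$mother@hap1[1], 1L)
  expect_identical(res$mother@hap1[2], 1L)
  expect_identical(res$mother@hap2[2], 0L)
  expect_true(is.na(res$father@hap1[3]) && is.na(res$mother@hap1[3]))
  expect_identical(res$inconsistent, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_true(is.na(res$father@hap1[4]))
  expect_identical(res$father@hap1[5], 0L)
  # hom parent at an uninformative site stays trivially phased
  expect_identical(res$father@hap1[2], 0L)
})

test_that("concordance counts agreement under the best orientation", {
  n <- 10
  st <- toySites(n)
  a <- ParentalHaplotypes(st, rep(c(0L, 1L), 5), rep(c(1L, 0L), 5))
  expect_equal(haplotypeConcordance(a, a), 1.0)
  # one site flipped
  b1 <- a@hap1; b2 <- a@hap2
  b1[4] <- a@hap2[4]; b2[4] <- a@hap1[4]
  b <- ParentalHaplotypes(st, b1, b2)
  expect_equal(haplotypeConcordance(a, b), 0.9)
  expect_equal(haplotypeConcordance(b, a), 0.9)  # symmetric
  # global hap1/hap2 swap is orientation, not discordance
  swapped <- ParentalHaplotypes(st, a@hap2, a@hap1)
  expect_equal(haplotypeConcordance(a, swapped), 1.0)
  # hom-only overlap is an error, not NaN
  hom <- ParentalHaplotypes(st, rep(0L, n), rep(0L, n))
  expect_error(haplotypeConcordance(hom, hom), "no commonly phased")
})

test_that("switch error is zero for perfect phase and counts flips otherwise", {
  n <- 8
  st <- toySites(n)
  truth <- ParentalHaplotypes(st, rep(c(0L, 1L), 4), rep(c(1L, 0L), 4))
  expect_equal(switchErrorRate(truth, truth), 0)
  # flip orientation from site 5 onward: exactly one switch in 7 intervals
  h1 <- truth@hap1; h2 <- truth@hap2
  h1[5:8] <- truth@hap2[5:8]; h2[5:8] <- truth@hap1[5:8]
  cand <- ParentalHaplotypes(st, h1, h2)
  expect_equal(switchErrorRate(cand, truth), 1 / 7)
})

test_that("switch error vanishes when the truth haplotypes are in the panel", {
  cfg <- simConfig(nPanelSamples = 60, nSites = 40)
  panel <- simulatePanel(cfg, seed = 77)
  st <- sites(panel)
  for (s in c(3L, 17L)) {
    h1 <- haplotypes(panel)[2 * s - 1, ]
    h2 <- haplotypes(panel)[2 * s, ]
    gt <- toyGenotypes(st, a = pmin(h1, h2), b = pmax(h1, h2))
    ph <- phaseWithPanel(gt, panel)
    truth <- ParentalHaplotypes(st, h1, h2, source = "truth")
    if (sum(h1 + h2 == 1) >= 2) {
      expect_equal(switchErrorRate(ph, truth), 0)
    }
  }
})
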