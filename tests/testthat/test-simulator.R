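# Simulator: determinism, configured moments, and the downsampling
# experiment structure. Small sizes keep the statistical checks cheap;
# binomial/Poisson oracles use 3-sigma bands.

test_that("panel simulation is deterministic and respects its moments", {
  cfg <- simConfig(nPanelSamples = 100, nSites = 40, nFfSites = 0)
  p1 <- simulatePanel(cfg, seed = 91)
  p2 <- simulatePanel(cfg, seed = 91)
  expect_identical(haplotypes(p1), haplotypes(p2))
  expect_identical(sites(p1), sites(p2))
  p3 <- simulatePanel(cfg, seed = 92)
  expect_false(identical(haplotypes(p1), haplotypes(p3)))
  expect_equal(nHaplotypes(p1), 200L)  # H = 2n
  # realized carrier count within 3 SD of hapFreq * H
  cfg2 <- simConfig(nPanelSamples = 500, nSites = 30, nFfSites = 0,
                    pathogenicVariants = data.frame(
                      id = "v", pos = 5248166, ref = "A", alt = "T",
                      kind = "SNP", cnv_end = NA_integer_, hapFreq = 0.05
                    ))
  p <- simulatePanel(cfg2, seed = 93)
  carriers <- sum(lengths(pathogenicFlags(p)) > 0)
  expect_lt(abs(carriers - 1000 * 0.05), 3 * sqrt(1000 * 0.05 * 0.95))
  # marker allele-frequency spectrum is centred as configured (the founder
  # process adds sampling noise around the drawn frequencies)
  af <- panelAlleleFreq(p)
  marker <- is.na(sites(p)$id)
  expect_gt(mean(af[marker]), 0.3)
  expect_lt(mean(af[marker]), 0.7)
})

test_that("families are at-risk couples and recombination behaves", {
  cfg <- simConfig(nPanelSamples = 50, nSites = 30, nFfSites = 10)
  panel <- simulatePanel(cfg, seed = 94)
  fam <- simulateFamily(panel, cfg, seed = 95)
  expect_identical(fam$father,
                   simulateFamily(panel, cfg, seed = 95)$father)
  # both parents carry at least one flagged haplotype
  for (parent in list(fam$father, fam$mother)) {
    labs <- pathogenicFlags(parent)
    expect_gte(length(labs$hap1) + length(labs$hap2), 1)
  }
  # zero recombination: the fetal haplotype is one parental haplotype
  cfg0 <- simConfig(nPanelSamples = 50, nSites = 30, nFfSites = 0,
                    recombRate = 1e-300)
  panel0 <- simulatePanel(cfg0, seed = 94)
  fam0 <- simulateFamily(panel0, cfg0, seed = 96)
  expect_true(identical(fam0$fetus$pat, fam0$father@hap1) ||
                identical(fam0$fetus$pat, fam0$father@hap2))
  # breakpoint counts are Poisson(rate * length): mean within 3 SD
  cfgR <- simConfig(nPanelSamples = 10, nSites = 10, nFfSites = 0,
                    recombRate = 1e-5)  # lambda = 2 per meiosis
  panelR <- simulatePanel(cfgR, seed = 97)
  set.seed(98)
  n_bp <- vapply(1:2000, function(i) {
    length(simulateFamily(panelR, cfgR, seed = i)$breakpoints$pat)
  }, numeric(1))
  lambda <- 1e-5 * cfgR$regionLength
  expect_lt(abs(mean(n_bp) - lambda), 3 * sqrt(lambda / 2000))
})

test_that("plasma counts match the mixture model (binomial oracle)", {
  cfg <- simConfig(nPanelSamples = 50, nSites = 40, nFfSites = 0,
                   plasmaDepth = 10000, depthSdLog = 1e-4, f = 0.2)
  panel <- simulatePanel(cfg, seed = 99)
  fam <- simulateFamily(panel, cfg, seed = 100)
  cnt <- simulateCfdna(fam$mother, fam$fetus, cfg, seed = 101)
  expect_identical(cnt@altDepth,
                   simulateCfdna(fam$mother, fam$fetus, cfg,
                                 seed = 101)@altDepth)
  gM <- genotypeDosage(fam$mother)
  # paternal-specific sites: mother 0/0, fetus carries one paternal alt
  spec <- which(gM == 0 & fam$fetus$mat == 0 & fam$fetus$pat == 1)
  for (j in spec) {
    mu <- 0.2 / 2
    mu_adj <- mu * (1 - cfg$errorRate) + (1 - mu) * cfg$errorRate
    sd3 <- 3 * sqrt(mu_adj * (1 - mu_adj) / cnt@depth[j])
    expect_lt(abs(cnt@altDepth[j] / cnt@depth[j] - mu_adj), sd3 + 0.01)
  }
  # f = 0: maternal-het sites concentrate at 1/2
  cfg0 <- simConfig(nPanelSamples = 50, nSites = 40, nFfSites = 0,
                    plasmaDepth = 10000, depthSdLog = 1e-4, f = 0)
  cnt0 <- simulateCfdna(fam$mother, list(mat = fam$mother@hap1,
                                         pat = fam$mother@hap2),
                        cfg0, seed = 102, f = 0)
  het <- which(gM == 1)
  ratios <- cnt0@altDepth[het] / cnt0@depth[het]
  expect_lt(max(abs(ratios - 0.5)), 0.03)
})

test_that("the downsampling experiment is deterministic and well-formed", {
  cfg <- simConfig(nPanelSamples = 60, nSites = 60, nFfSites = 60)
  panel <- simulatePanel(cfg, seed = 103)
  tg <- defaultTarget(cfg)
  fams <- lapply(1:3, function(i) simulateFamily(panel, cfg, seed = 200 + i))
  cnts <- lapply(1:3, function(i) simulateCfdna(fams[[i]]$mother,
                                                fams[[i]]$fetus, cfg,
                                                seed = 300 + i))
  df <- downsampleExperiment(panel, fams, cnts, tg,
                             fractions = c(1/2, 1/4), nAbsolute = 10,
                             nReps = 2, seed = 7)
  df2 <- downsampleExperiment(panel, fams, cnts, tg,
                              fractions = c(1/2, 1/4), nAbsolute = 10,
                              nReps = 2, seed = 7)
  expect_identical(df, df2)
  expect_equal(df$level[1], "full")
  expect_setequal(unique(df$level), c("full", "1/2", "1/4", "10"))
  expect_equal(sum(df$level == "1/2"), 2L)  # nReps rows per level
  expect_equal(df$n_samples[df$level == "full"][1], 60)
  expect_true(all(df$accuracy >= 0 & df$accuracy <= 1))
  expect_true(all(df$no_call_rate >= 0 & df$no_call_rate <= 1))
  p <- plotDownsampleExperiment(df)
  expect_s3_class(p, "ggplot")
})
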