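# Dosage HMM: expected alt fractions, Viterbi/forward-backward against
# exhaustive path enumeration, confidence scores, and calling rules.

# independent copy-counting oracle: enumerate the four genome copies in
# plasma explicitly (mother's two haplotypes at (1-f)/2 each, fetal
# maternal+paternal haplotypes at f/2 each) and sum the alt copies
oracleMu <- function(motherAlleles, fetalMatAllele, fetalPatAllele, f) {
  sum(c((1 - f) / 2 * motherAlleles,
        f / 2 * c(fetalMatAllele, fetalPatAllele)))
}

# exhaustive 2-state path enumeration for small S: joint log-probability
# of every path and the data
enumeratePaths <- function(emis, pos, recombRate) {
  S <- ncol(emis)
  lflip <- log(0.5 * (1 - exp(-2 * recombRate * diff(pos))))
  lstay <- log(1 - 0.5 * (1 - exp(-2 * recombRate * diff(pos))))
  paths <- as.matrix(expand.grid(rep(list(1:2), S)))
  lp <- apply(paths, 1, function(s) {
    out <- log(0.5) + emis[s[1], 1]
    for (j in seq_len(S)[-1]) {
      out <- out + (if (s[j] == s[j - 1]) lstay[j - 1] else lflip[j - 1]) +
        emis[s[j], j]
    }
    out
  })
  list(paths = paths, lp = lp)
}

test_that("expected alt fractions match the copy-counting oracle on a grid", {
  for (f in c(0, 0.05, 0.1, 0.2, 0.35, 0.5)) {
    # PATERNAL: mother hom (g), father het with alt on one haplotype
    for (g in c(0L, 1L)) {
      for (hyp in c("HAP_P", "HAP_N")) {
        for (altOnP in c(TRUE, FALSE)) {
          ap <- if (altOnP) 1L else 0L
          an <- 1L - ap
          transmitted <- if (hyp == "HAP_P") ap else an
          expect_equal(
            expectedAltFraction("PATERNAL", ap, an, g, hyp, f),
            oracleMu(c(g, g), g, transmitted, f),
            info = sprintf("PATERNAL f=%g g=%d hyp=%s", f, g, hyp)
          )
        }
      }
    }
    # MATERNAL types: mother het, father contribution fixed
    for (cls in c("MATERNAL_T1", "MATERNAL_T2")) {
      for (p_all in c(0L, 1L)) {
        for (hyp in c("HAP_P", "HAP_N")) {
          for (altOnP in c(TRUE, FALSE)) {
            ap <- if (altOnP) 1L else 0L
            an <- 1L - ap
            transmitted <- if (hyp == "HAP_P") ap else an
            expect_equal(
              expectedAltFraction(cls, ap, an, p_all, hyp, f),
              oracleMu(c(0L, 1L), transmitted, p_all, f),
              info = sprintf("%s f=%g p=%d hyp=%s", cls, f, p_all, hyp)
            )
          }
        }
      }
    }
  }
  # at f = 0 the maternal hypotheses are indistinguishable at 1/2
  expect_equal(expectedAltFraction("MATERNAL_T1", 1L, 0L, 0L, "HAP_P", 0),
               expectedAltFraction("MATERNAL_T1", 1L, 0L, 0L, "HAP_N", 0))
  # hand-computed spot values: paternal f=0.2 alt transmitted, mother hom-ref
  expect_equal(expectedAltFraction("PATERNAL", 1L, 0L, 0L, "HAP_P", 0.2), 0.10)
  expect_equal(expectedAltFraction("MATERNAL_T1", 1L, 0L, 0L, "HAP_P", 0.2), 0.5)
  expect_equal(expectedAltFraction("MATERNAL_T1", 1L, 0L, 0L, "HAP_N", 0.2), 0.40)
  expect_error(expectedAltFraction("PATERNAL", 1L, 1L, 0L, "HAP_P", 0.1),
               "heterozygous")
})

test_that("a single overwhelming site decodes to the supported haplotype", {
  st <- toySites(1)
  info <- toyInformative(st, "PATERNAL")
  counts <- toyCounts(st, 1000L, 100L)  # alt fraction 0.10 = f/2
  path <- viterbiDecode(info, counts, f = 0.2, hmmConfig())
  expect_equal(path$states, "HAP_P")
  expect_gt(path$postDecoded, 0.999)
})

test_that("Viterbi and posteriors equal exhaustive path enumeration (property)", {
  set.seed(71)
  cfg <- hmmConfig()
  for (rep in 1:10) {
    S <- sample(3:8, 1)
    st <- toySites(S, by = sample(c(2000, 50000), 1))
    cls <- sample(c("PATERNAL", "MATERNAL_T1"), S, replace = TRUE)
    info <- toyInformative(st, cls, other_allele = 0L)
    f <- runif(1, 0.08, 0.25)
    depth <- rpois(S, 150)
    truth_state <- sample(1:2, 1)
    mu <- vapply(seq_len(S), function(j) expectedAltFraction(
      cls[j], 1L, 0L, 0L, c("HAP_P", "HAP_N")[truth_state], f
    ), numeric(1))
    counts <- toyCounts(st, depth, rbinom(S, depth, mu))
    path <- viterbiDecode(info, counts, f, cfg)
    enum <- enumeratePaths(path$emissionLog, st$pos, cfg$recombRate)
    # Viterbi path log-probability equals the enumerated maximum
    expect_equal(path$logLik, max(enum$lp), tolerance = 1e-9)
    best <- enum$paths[which.max(enum$lp), ]
    expect_equal(path$states, c("HAP_P", "HAP_N")[best])
    # forward-backward posterior at each site equals the brute-force sum
    for (j in seq_len(S)) {
      brute_post <- sum(exp(enum$lp[enum$paths[, j] == 1])) / sum(exp(enum$lp))
      expect_equal(unname(path$posterior["HAP_P", j]), brute_post,
                   tolerance = 1e-9)
    }
    # posteriors sum to one over the two states
    expect_equal(colSums(path$posterior), rep(1, S), tolerance = 1e-9)
  }
})

test_that("a simulated recombination switches the path exactly once, in place", {
  st <- toySites(8, by = 20000)
  info <- toyInformative(st, "PATERNAL")
  f <- 0.2
  mu <- c(rep(0.10, 3), rep(0.0, 5))  # HAP_P then HAP_N after site 3
  set.seed(72)
  counts <- toyCounts(st, 2000L, rbinom(8, 2000L, pmax(mu, 0.005)))
  path <- viterbiDecode(info, counts, f, hmmConfig())
  expect_equal(path$states, c(rep("HAP_P", 3), rep("HAP_N", 5)))
  blocks <- pathBlocks(path)
  expect_equal(nrow(blocks), 2L)
  expect_equal(blocks$end_idx, c(3L, 8L))
  # extended intervals partition the chromosome at the block midpoint
  expect_equal(blocks$ext_end[1], (st$pos[3] + st$pos[4]) / 2)
  expect_equal(blocks$ext_start[1], -Inf)
  expect_equal(blocks$ext_end[2], Inf)
})

test_that("confidence score is anchored at the target and handles edge cases", {
  # zero informative sites: CS = 0 and a no-call, never a crash
  st0 <- toySites(0)
  tg <- targetGene("HBB", "11", 5200000, 5204000,
                   siteTable("11", 5202000, "A", "T", id = "c.52A>T"))
  empty <- viterbiDecode(toyInformative(st0, character(0)),
                         toyCounts(st0, integer(0), integer(0)),
                         f = 0.15, hmmConfig())
  expect_length(empty$states, 0)
  cs0 <- confidenceScore(empty, pathBlocks(empty), tg)
  expect_equal(cs0, 0)
  call0 <- callAllele(empty, pathBlocks(empty), cs0, tg)
  expect_equal(call0$call, "no_call")
  expect_equal(call0$nSnpsHapP + call0$nSnpsHapN, 0L)

  # f = 0: maternal hypotheses indistinguishable, CS = 1/2
  st <- toySites(4)
  info <- toyInformative(st, "MATERNAL_T1")
  counts <- toyCounts(st, 200L, 100L)
  path <- viterbiDecode(info, counts, f = 0, hmmConfig())
  expect_equal(confidenceScore(path, pathBlocks(path), toyTarget(st, NULL)),
               0.5, tolerance = 1e-9)

  # 4-site toy: CS equals the brute-force posterior at the anchor site
  set.seed(73)
  info2 <- toyInformative(toySites(4), "PATERNAL")
  counts2 <- toyCounts(toySites(4), rep(120L, 4),
                       rbinom(4, 120L, c(0.07, 0.08, 0.01, 0.06)))
  cfg <- hmmConfig()
  path2 <- viterbiDecode(info2, counts2, f = 0.15, cfg)
  blocks2 <- pathBlocks(path2)
  tg2 <- targetGene("HBB", "11", toySites(4)$pos[2] - 100,
                    toySites(4)$pos[2] + 100,
                    siteTable("11", toySites(4)$pos[2] + 1, "A", "T",
                              id = "x"))
  cs <- confidenceScore(path2, blocks2, tg2)
  enum <- enumeratePaths(path2$emissionLog, toySites(4)$pos, cfg$recombRate)
  anchor <- 2  # nearest informative site to the target midpoint
  dec <- match(path2$states[anchor], c("HAP_P", "HAP_N"))
  brute <- sum(exp(enum$lp[enum$paths[, anchor] == dec])) / sum(exp(enum$lp))
  expect_equal(cs, brute, tolerance = 1e-9)
})

test_that("no-call rules fire on low CS and on unspanned two-block paths", {
  st <- toySites(5)
  tg <- toyTarget(st, NULL)
  info <- toyInformative(st, "PATERNAL")
  counts <- toyCounts(st, 500L, c(48, 50, 2, 1, 0))
  cfg <- hmmConfig()
  path <- viterbiDecode(info, counts, f = 0.2, cfg)
  blocks <- pathBlocks(path)
  # synthetic CS just below / at the threshold
  expect_equal(callAllele(path, blocks, 0.98, tg, cfg)$call, "no_call")
  expect_false(callAllele(path, blocks, 0.99, tg, cfg)$call == "no_call")
  # two blocks, target outside both cores -> no-call even at CS 1
  tg_out <- targetGene("HBB", "11", st$pos[2] + 100, st$pos[3] - 100,
                       siteTable("11", st$pos[2] + 150, "A", "T", id = "x"))
  b2 <- pathBlocks(path)
  expect_gte(nrow(b2), 2)
  expect_true(is.na(hapdose:::spanningBlockIndex(b2, tg_out)))
  expect_equal(callAllele(path, b2, 1.0, tg_out, cfg)$call, "no_call")
  # supporting-SNP counts come from per-site ML comparison
  call <- callAllele(path, blocks, 1.0, tg, cfg, variantId = "v")
  expect_equal(call$nSnpsHapP + call$nSnpsHapN,
               sum(path$emissionLog[1, ] != path$emissionLog[2, ]))
})

test_that("inferFetus runs the two-step order and honors CNV exclusion", {
  set.seed(74)
  n <- 30
  st <- toySites(n, by = 4000, ids = "c.52A>T")
  # father: carrier on hap1; het at odd sites; mother: carrier on hap1,
  # het at even sites => paternal sites odd, maternal T1 even
  fh1 <- rep(c(1L, 0L), n / 2); fh1[1] <- 1L
  fh2 <- rep(0L, n)
  mh1 <- rep(c(0L, 1L), n / 2); mh1[1] <- 1L
  mh2 <- rep(0L, n); mh2[1] <- 0L
  father <- ParentalHaplotypes(st, fh1, fh2)
  mother <- ParentalHaplotypes(st, mh1, mh2)
  tg <- targetGene("HBB", st$chrom[1], st$pos[1] - 100, st$pos[1] + 100,
                   st[1, , drop = FALSE])
  f <- 0.15
  fetus_mat <- mh1  # fetus inherits both pathogenic haplotypes
  fetus_pat <- fh1
  mu <- (1 - f) / 2 * (mh1 + mh2) + f / 2 * (fetus_mat + fetus_pat)
  depth <- rep(300L, n)
  counts <- CfdnaCounts(st, depth, rbinom(n, depth, pmin(pmax(mu, 0.003),
                                                         0.997)),
                        ff = f)
  res <- inferFetus(father, mother, counts, tg)[[1]]
  expect_equal(res$paternal$call, "pathogenic")
  expect_equal(res$maternal$call, "pathogenic")
  expect_equal(res$paternal$variantId, "c.52A>T")
  expect_gte(res$maternal$cs, 0.99)
  # maternal step received type-2 sites only where paternal blocks resolved
  expect_true(all(res$maternalPath$sites$class %in%
                    c("MATERNAL_T1", "MATERNAL_T2")))

  # the pathogenic site itself is the only shared-id site; now give the
  # mother a CNV spanning a chunk of the region: those SNPs must vanish
  cnv_st <- rbind(st, siteTable(st$chrom[1], st$pos[5] - 10, ref = "N",
                                alt = "<CNV>", kind = "CNV",
                                cnv_end = st$pos[10] + 10, id = "--SEA"))
  cnv_st <- cnv_st[order(cnv_st$chrom, cnv_st$pos), , drop = FALSE]
  rownames(cnv_st) <- NULL
  ci <- which(cnv_st$kind == "CNV")
  ins <- function(v, x) append(v, x, after = ci - 1L)
  father2 <- ParentalHaplotypes(cnv_st, ins(fh1, 0L), ins(fh2, 0L))
  mother2 <- ParentalHaplotypes(cnv_st, ins(mh1, 1L), ins(mh2, 0L))
  counts2 <- CfdnaCounts(cnv_st, ins(depth, 0L),
                         ins(counts@altDepth, 0L), ff = f)
  tg2 <- targetGene("HBB", st$chrom[1], st$pos[1] - 100, st$pos[1] + 100,
                    st[1, , drop = FALSE])
  res2 <- inferFetus(father2, mother2, counts2, tg2)[[1]]
  excluded <- st$pos[5:10]
  expect_false(any(excluded %in% res2$paternalPath$sites$pos))
  expect_false(any(excluded %in% res2$maternalPath$sites$pos))
})

test_that("parents needing no decoding are forced, never decoded", {
  st <- toySites(10, ids = "c.52A>T")
  tg <- toyTarget(st)
  # father homozygous pathogenic; mother het carrier
  father <- ParentalHaplotypes(st, c(1L, rep(0L, 9)), c(1L, rep(0L, 9)))
  mh1 <- c(1L, rep(c(1L, 0L), length.out = 9))
  mother <- ParentalHaplotypes(st, mh1, rep(0L, 10))
  f <- 0.15
  mu <- (1 - f) / 2 * (mh1 + 0) + f / 2 * (mh1 + c(1L, rep(0L, 9)))
  set.seed(75)
  counts <- CfdnaCounts(st, rep(250L, 10),
                        rbinom(10, 250L, pmin(pmax(mu, 0.003), 0.997)),
                        ff = f)
  res <- inferFetus(father, mother, counts, tg)[[1]]
  expect_equal(res$paternal$call, "pathogenic")
  expect_equal(res$paternal$cs, 1)
  expect_equal(res$paternal$flags, "uninformative-by-genotype")
  expect_null(res$paternalPath)
  # father with no het sites near target: zero paternal informative sites
  father0 <- ParentalHaplotypes(st, c(0L, rep(0L, 9)), c(1L, rep(0L, 9)))
  res0 <- inferFetus(father0, mother, counts, tg)[[1]]
  expect_equal(res0$paternal$call, "no_call")
  expect_equal(res0$paternal$cs, 0)
  # maternal decoding proceeded on type-1 sites alone
  expect_true(all(res0$maternalPath$sites$class == "MATERNAL_T1"))
})
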