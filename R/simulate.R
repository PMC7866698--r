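## Synthetic data with the statistical structure the pipeline assumes:
## founder-haplotype copying panels (LD decaying with distance, pathogenic
## variants riding consistent founder backgrounds), at-risk families drawn
## from the same population process, plasma read counts from the maternal/
## fetal mixture, and the in-silico panel-downsampling experiment.

#' Simulation configuration
#'
#' Defaults emulate a capture panel around the beta-globin locus (hg19
#' coordinates) in a carrier-screening population: marker allele
#' frequencies from a symmetric Beta(0.8, 0.8) truncated to [0.05, 0.95]
#' (a capture design enriched for informative heterozygotes), plasma depth
#' log-normal around 177x and parental gDNA around 203x, fetal fraction
#' 0.15, per-read error 0.005.
#'
#' @param nPanelSamples panel individuals (haplotypes = 2x this).
#' @param nSites marker SNPs across the region.
#' @param nFfSites unlinked common SNPs simulated as a dedicated
#'   fetal-fraction marker backbone (off the target chromosome; parents'
#'   genotypes independent draws at the site's allele frequency). Such a
#'   backbone of polymorphic markers away from the disease locus is how
#'   cfDNA assays obtain enough opposite-homozygote sites for the f
#'   estimate.
#' @param ffMafRange minor-allele-frequency range of the backbone SNPs.
#' @param chrom,regionStart,regionLength simulated region.
#' @param nFounders founder haplotypes behind the copying process.
#' @param pathogenicVariants \code{data.frame(id, pos, ref, alt, kind,
#'   cnv_end, hapFreq)}: pathogenic variants and their haplotype frequency
#'   in the (carrier-enriched) panel.
#' @param founderSwitchRate per-bp founder-switch intensity of the copying
#'   process (controls LD decay).
#' @param mutationRate per-site copying mutation probability (marker sites
#'   only; pathogenic sites stay faithful to their founder).
#' @param recombRate per-bp meiotic recombination rate for fetal gametes.
#' @param afShape,afRange Beta shape and truncation for marker allele
#'   frequencies.
#' @param plasmaDepth,gdnaDepth mean sequencing depths.
#' @param depthSdLog log-sd of the log-normal depth distributions.
#' @param f true fetal fraction.
#' @param errorRate per-read miscall probability.
#' @return a \code{"SimConfig"} list.
#' @export
simConfig <- function(nPanelSamples = 500, nSites = 220, chrom = "11",
                      regionStart = 5148000, regionLength = 200000,
                      nFfSites = 200, ffMafRange = c(0.2, 0.5),
                      nFounders = 12,
                      pathogenicVariants = data.frame(
                        id = "c.126_129delCTTT", pos = 5248166,
                        ref = "CTTTT", alt = "C", kind = "INDEL",
                        cnv_end = NA_integer_, hapFreq = 0.10,
                        stringsAsFactors = FALSE
                      ),
                      founderSwitchRate = 5e-6, mutationRate = 0.005,
                      recombRate = 1.2e-8, afShape = c(0.8, 0.8),
                      afRange = c(0.05, 0.95), plasmaDepth = 177,
                      gdnaDepth = 203, depthSdLog = 0.4, f = 0.15,
                      errorRate = 0.005) {
  stopifnot(nPanelSamples >= 1, nSites >= 1, nFounders >= 2,
            all(pathogenicVariants$hapFreq > 0),
            all(pathogenicVariants$hapFreq < 1),
            f >= 0, f <= 0.5)
  if (nrow(pathogenicVariants) >= nFounders) {
    stop("need fewer pathogenic variants than founders")
  }
  structure(as.list(environment()), class = "SimConfig")
}

#' Default target gene for the simulated region
#'
#' The beta-globin (HBB) interval, hg19, with the configured pathogenic
#' variants that fall inside it.
#'
#' @param cfg a [simConfig()].
#' @return a \code{TargetGene}.
#' @export
defaultTarget <- function(cfg) {
  pv <- cfg$pathogenicVariants
  st <- siteTable(cfg$chrom, pv$pos, pv$ref, pv$alt, pv$kind, pv$cnv_end,
                  pv$id)
  targetGene("HBB", cfg$chrom, 5246696, 5248301, st)
}

## One copying realization: founder path with distance-dependent switches,
## founder alleles copied with mutation at marker sites.
copyHaplotype <- function(gen) {
  S <- length(gen$pos)
  p_sw <- -expm1(-gen$switchRate * diff(gen$pos))
  switches <- stats::runif(S - 1) < p_sw
  seg <- cumsum(c(1L, switches))
  donors <- sample.int(nrow(gen$founders), max(seg), replace = TRUE,
                       prob = gen$weights)
  hap <- gen$founders[cbind(donors[seg], seq_len(S))]
  flip <- stats::runif(S) < gen$mutationRate & !gen$isPathogenic
  hap[flip] <- 1L - hap[flip]
  hap
}

#' Simulate a phased reference panel
#'
#' Marker allele frequencies are drawn once; founder haplotypes are
#' Bernoulli draws at those frequencies; each pathogenic variant is placed
#' on its own founder, whose copying weight equals the variant's haplotype
#' frequency, so carriers share a founder background with LD decaying over
#' distance and the realized carrier count is binomial around
#' \code{hapFreq * H}. The generator state is attached (attribute
#' \code{"generator"}) so families can be drawn from the same population
#' process.
#'
#' @param cfg a [simConfig()].
#' @param seed integer seed (mandatory; all simulator randomness is
#'   reproducible from it).
#' @return a [PhasedPanel-class].
#' @export
simulatePanel <- function(cfg, seed) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(seed)
  pv <- cfg$pathogenicVariants
  marker_pos <- sort(sample.int(cfg$regionLength, cfg$nSites)) + cfg$regionStart
  marker_pos <- setdiff(marker_pos, pv$pos)
  st <- rbind(
    siteTable(cfg$chrom, marker_pos,
              ref = sample(c("A", "C", "G", "T"), length(marker_pos), TRUE),
              alt = "X", kind = "SNP"),
    siteTable(cfg$chrom, pv$pos, pv$ref, pv$alt, pv$kind, pv$cnv_end, pv$id)
  )
  st <- st[order(st$chrom, st$pos), , drop = FALSE]
  # distinct ref/alt labels per position keep (chrom,pos,ref,alt) unique
  mk <- st$alt == "X"
  st$alt[mk] <- vapply(seq_len(sum(mk)), function(i) {
    sample(setdiff(c("A", "C", "G", "T"), st$ref[mk][i]), 1)
  }, character(1))
  rownames(st) <- NULL
  S <- nrow(st)
  K <- cfg$nFounders
  af <- pmin(pmax(stats::rbeta(S, cfg$afShape[1], cfg$afShape[2]),
                  cfg$afRange[1]), cfg$afRange[2])
  founders <- matrix(stats::rbinom(K * S, 1L, rep(af, each = K)), nrow = K)
  is_path <- !is.na(st$id)
  path_idx <- which(is_path)
  # one founder per pathogenic variant; remaining weight shared equally
  founders[, path_idx] <- 0L
  for (v in seq_along(path_idx)) founders[v, path_idx[v]] <- 1L
  pv_ord <- match(st$id[path_idx], pv$id)
  weights <- rep((1 - sum(pv$hapFreq)) / (K - nrow(pv)), K)
  weights[seq_along(path_idx)] <- pv$hapFreq[pv_ord]
  gen <- list(founders = founders, weights = weights, pos = st$pos,
              switchRate = cfg$founderSwitchRate,
              mutationRate = cfg$mutationRate, isPathogenic = is_path)
  H <- 2L * cfg$nPanelSamples
  haps <- t(vapply(seq_len(H), function(i) copyHaplotype(gen), integer(S)))
  panel <- PhasedPanel(st, haps)
  attr(panel, "generator") <- gen
  panel
}

noisyGenotypes <- function(st, hap1, hap2, meanDepth, sdLog, errorRate) {
  S <- nrow(st)
  dosage <- hap1 + hap2
  depth <- pmax(1L, as.integer(round(stats::rlnorm(
    S, log(meanDepth) - sdLog^2 / 2, sdLog
  ))))
  p <- (dosage / 2) * (1 - errorRate) + (1 - dosage / 2) * errorRate
  alt_depth <- stats::rbinom(S, depth, p)
  cbind(st, data.frame(
    allele_a = pmin(hap1, hap2), allele_b = pmax(hap1, hap2),
    phased = FALSE, depth = depth, alt_depth = alt_depth
  ))
}

#' Simulate an at-risk family
#'
#' Parents are fresh copying realizations from the panel's population
#' process, each conditioned (by rejection) to carry at least one
#' configured pathogenic variant — the at-risk-couple condition. The fetus
#' receives one recombined haplotype per parent (breakpoint count Poisson
#' with intensity \code{recombRate * regionLength}, positions uniform).
#' In addition to the target-region sites, \code{cfg$nFfSites} unlinked
#' fetal-fraction marker SNPs are simulated (independent parental alleles,
#' independent fetal transmission per site). Parental gDNA genotypes are
#' emitted with log-normal depth noise; the genotype calls themselves are
#' error-free.
#'
#' @param panel a [simulatePanel()] result (must carry its generator).
#' @param cfg the [simConfig()] used to build the panel.
#' @param seed integer seed.
#' @return list: \code{father}, \code{mother} (truth
#'   [ParentalHaplotypes-class]), \code{fatherGt}, \code{motherGt}
#'   (genotype data.frames), \code{fetus} (list \code{mat}, \code{pat}:
#'   transmitted allele vectors), \code{transmitted} (which parental
#'   haplotype the fetus carries at each site, per parent), and
#'   \code{breakpoints}.
#' @export
simulateFamily <- function(panel, cfg, seed) {
  gen <- attr(panel, "generator")
  if (is.null(gen)) stop("panel lacks its generator state; use simulatePanel()")
  set.seed(seed)
  st <- sites(panel)
  path_idx <- which(!is.na(st$id))
  if (sum(vapply(pathogenicFlags(panel), length, integer(1)) > 0) == 0) {
    stop("panel carries no pathogenic haplotypes")
  }
  draw_carrier <- function() {
    for (i in seq_len(1000)) {
      h <- copyHaplotype(gen)
      if (any(h[path_idx] == 1L)) return(h)
    }
    stop("failed to draw a carrier haplotype; is hapFreq too small?")
  }
  make_parent <- function() list(h1 = draw_carrier(), h2 = copyHaplotype(gen))
  fa <- make_parent()
  mo <- make_parent()
  meiosis <- function(h1, h2) {
    n_bp <- stats::rpois(1, cfg$recombRate * cfg$regionLength)
    bp <- sort(stats::runif(n_bp, cfg$regionStart,
                            cfg$regionStart + cfg$regionLength))
    phase_idx <- (findInterval(st$pos, bp) + sample(0:1, 1)) %% 2L + 1L
    list(hap = ifelse(phase_idx == 1L, h1, h2), from = phase_idx,
         breakpoints = bp)
  }
  tp <- meiosis(fa$h1, fa$h2)
  tm <- meiosis(mo$h1, mo$h2)

  # unlinked fetal-fraction backbone: independent parental alleles,
  # independent transmission per site
  nf <- cfg$nFfSites %||% 0L
  if (nf > 0) {
    maf <- stats::runif(nf, cfg$ffMafRange[1], cfg$ffMafRange[2])
    q <- ifelse(stats::runif(nf) < 0.5, maf, 1 - maf)
    ff_st <- siteTable("20", 20e6 + 5000L * seq_len(nf),
                       ref = rep(c("A", "C", "G", "T"), length.out = nf),
                       alt = rep(c("G", "T", "A", "C"), length.out = nf))
    draw <- function() stats::rbinom(nf, 1L, q)
    fa_f <- list(h1 = draw(), h2 = draw())
    mo_f <- list(h1 = draw(), h2 = draw())
    pick <- function(p) ifelse(stats::runif(nf) < 0.5, p$h1, p$h2)
    comb <- function(region, ffs) {
      full_st <- rbind(st, ff_st)
      ord <- order(full_st$chrom, full_st$pos)
      list(st = `rownames<-`(full_st[ord, , drop = FALSE], NULL),
           v = c(region, ffs)[ord], ord = ord)
    }
    c1f <- comb(fa$h1, fa_f$h1); c2f <- comb(fa$h2, fa_f$h2)
    c1m <- comb(mo$h1, mo_f$h1); c2m <- comb(mo$h2, mo_f$h2)
    full_st <- c1f$st
    fa <- list(h1 = c1f$v, h2 = c2f$v)
    mo <- list(h1 = c1m$v, h2 = c2m$v)
    fetus_mat <- comb(tm$hap, pick(mo_f))$v
    fetus_pat <- comb(tp$hap, pick(fa_f))$v
    trans_mat <- comb(tm$from, rep(NA_integer_, nf))$v
    trans_pat <- comb(tp$from, rep(NA_integer_, nf))$v
  } else {
    full_st <- st
    fetus_mat <- tm$hap; fetus_pat <- tp$hap
    trans_mat <- tm$from; trans_pat <- tp$from
  }
  list(
    father = ParentalHaplotypes(full_st, fa$h1, fa$h2, source = "truth"),
    mother = ParentalHaplotypes(full_st, mo$h1, mo$h2, source = "truth"),
    fatherGt = noisyGenotypes(full_st, fa$h1, fa$h2, cfg$gdnaDepth,
                              cfg$depthSdLog, cfg$errorRate),
    motherGt = noisyGenotypes(full_st, mo$h1, mo$h2, cfg$gdnaDepth,
                              cfg$depthSdLog, cfg$errorRate),
    fetus = list(mat = fetus_mat, pat = fetus_pat),
    transmitted = list(mat = trans_mat, pat = trans_pat),
    breakpoints = list(mat = tm$breakpoints, pat = tp$breakpoints)
  )
}

#' Simulate plasma cfDNA allele counts
#'
#' Per site, the expected alt fraction is obtained by copy counting over
#' the maternal/fetal mixture — maternal haplotypes weigh (1-f)/2 each,
#' fetal haplotypes f/2 each — then perturbed by the symmetric per-read
#' error; depth is log-normal around the plasma mean and alt reads are
#' binomial.
#'
#' @param mother truth [ParentalHaplotypes-class] of the mother.
#' @param fetus list with \code{mat}, \code{pat} transmitted allele vectors.
#' @param cfg a [simConfig()].
#' @param seed integer seed.
#' @param f fetal fraction override (default \code{cfg$f}).
#' @return a [CfdnaCounts-class] (fetal fraction left unestimated).
#' @export
simulateCfdna <- function(mother, fetus, cfg, seed, f = cfg$f) {
  set.seed(seed)
  st <- sites(mother)
  S <- nrow(st)
  mu <- (1 - f) / 2 * (mother@hap1 + mother@hap2) +
    f / 2 * (fetus$mat + fetus$pat)
  mu_adj <- mu * (1 - cfg$errorRate) + (1 - mu) * cfg$errorRate
  depth <- pmax(1L, as.integer(round(stats::rlnorm(
    S, log(cfg$plasmaDepth) - cfg$depthSdLog^2 / 2, cfg$depthSdLog
  ))))
  alt <- stats::rbinom(S, depth, mu_adj)
  CfdnaCounts(st, depth, alt)
}

#' True fetal allele strings at a target
#'
#' @param family a [simulateFamily()] result.
#' @param target a \code{TargetGene}.
#' @return character vector \code{c(mat, pat)}: variant id(s) or "N".
#' @export
trueAlleles <- function(family, target) {
  st <- sites(family$mother)
  idx <- which(st$id %in% target$pathogenicSites$id)
  one <- function(hap) {
    carried <- st$id[idx[hap[idx] == 1L]]
    if (length(carried) == 0) "N" else paste(carried, collapse = ",")
  }
  c(mat = one(family$fetus$mat), pat = one(family$fetus$pat))
}

#' Run the full pipeline on one simulated family
#'
#' Phase both parents against the panel, estimate the fetal fraction from
#' plasma counts, and decode both transmissions — the same path a real
#' sample takes.
#'
#' @param family a [simulateFamily()] result.
#' @param counts a [simulateCfdna()] result.
#' @param panel the [PhasedPanel-class] to phase against.
#' @param target a \code{TargetGene}.
#' @param cfg an [hmmConfig()].
#' @param minFfSites minimum sites for fetal-fraction estimation; families
#'   below it fall back to the configured truth via \code{fFallback}.
#' @param fFallback fetal fraction used when not estimable (default NULL:
#'   propagate the error).
#' @return list: \code{result} (the [inferFetus()] element), \code{truth}
#'   allele strings, \code{switchError} per parent, and the phased parents.
#' @export
runFamilyNipt <- function(family, counts, panel, target, cfg = hmmConfig(),
                          minFfSites = 10, fFallback = NULL) {
  fa <- phasePanelSubset(family$fatherGt, panel)
  mo <- phasePanelSubset(family$motherGt, panel)
  ffc <- tryCatch(
    estimateFetalFraction(counts, fa, mo, minSites = minFfSites),
    error = function(e) {
      if (is.null(fFallback)) stop(e)
      fetalFraction(counts) <- fFallback
      counts
    }
  )
  res <- inferFetus(fa, mo, ffc, target, cfg)[[1]]
  list(
    result = res,
    truth = trueAlleles(family, target),
    ff = fetalFraction(ffc),
    switchError = c(father = switchErrorRate(fa, family$father),
                    mother = switchErrorRate(mo, family$mother)),
    father = fa, mother = mo
  )
}

## Phase the panel-covered sites and carry the remaining sites through:
## off-panel homozygous sites are trivially phased, off-panel heterozygous
## or missing sites stay unphased (they serve fetal-fraction estimation,
## not dosage decoding).
phasePanelSubset <- function(genotypes, panel, ...) {
  in_panel <- siteKey(genotypes) %in% siteKey(sites(panel))
  if (all(in_panel)) return(phaseWithPanel(genotypes, panel, ...))
  ph <- phaseWithPanel(genotypes[in_panel, , drop = FALSE], panel, ...)
  g <- genotypes$allele_a + genotypes$allele_b
  hap1 <- ifelse(!is.na(g) & g != 1L, g %/% 2L, NA_integer_)
  hap2 <- hap1
  hap1[in_panel] <- ph@hap1
  hap2[in_panel] <- ph@hap2
  ParentalHaplotypes(genotypes[, SITE_COLS], hap1, hap2, source = "PBH")
}

subsamplePanel <- function(panel, sampleIdx) {
  keep <- as.vector(rbind(2L * sampleIdx - 1L, 2L * sampleIdx))
  sub <- PhasedPanel(sites(panel), haplotypes(panel)[keep, , drop = FALSE],
                     pathogenicFlags(panel)[keep])
  attr(sub, "generator") <- attr(panel, "generator")
  sub
}

#' Panel-downsampling experiment
#'
#' Re-runs phasing and fetal inference for a fixed set of simulated
#' families against nested random subsets of the reference panel —
#' fractions 1/2, 1/4, 1/6, 1/8, 1/12 and an absolute 50-sample level,
#' three independent draws each — and tabulates phasing switch error,
#' calling accuracy among called alleles, and the no-call rate. The full
#' panel is included as the reference level.
#'
#' @param panel full [PhasedPanel-class].
#' @param families list of [simulateFamily()] results.
#' @param countsList list of matching [simulateCfdna()] results.
#' @param target a \code{TargetGene}.
#' @param fractions fractional panel sizes.
#' @param nAbsolute absolute sample-count level (\code{NA} to skip).
#' @param nReps independent subsampling replicates per level.
#' @param seed integer seed.
#' @param cfg an [hmmConfig()].
#' @param fFallback fetal fraction for families where estimation fails.
#' @return tidy \code{data.frame}: \code{level, n_samples, rep,
#'   switch_error, accuracy, no_call_rate}.
#' @export
downsampleExperiment <- function(panel, families, countsList, target,
                                 fractions = c(1/2, 1/4, 1/6, 1/8, 1/12),
                                 nAbsolute = 50, nReps = 3, seed = 1,
                                 cfg = hmmConfig(), fFallback = 0.15) {
  stopifnot(length(families) == length(countsList))
  set.seed(seed)
  n_total <- nSamples(panel)
  sizes <- c(n_total, round(fractions * n_total),
             if (!is.na(nAbsolute)) nAbsolute)
  labels <- c("full", sprintf("1/%d", round(1 / fractions)),
              if (!is.na(nAbsolute)) as.character(nAbsolute))
  if (any(sizes < 1)) stop("a level yields fewer than one panel sample")
  rows <- list()
  for (li in seq_along(sizes)) {
    reps <- if (labels[li] == "full") 1L else nReps
    for (r in seq_len(reps)) {
      sub <- if (labels[li] == "full") panel else
        subsamplePanel(panel, sample.int(n_total, sizes[li]))
      outs <- mapply(function(fam, cnt) {
        run <- runFamilyNipt(fam, cnt, sub, target, cfg,
                             fFallback = fFallback)
        calls <- c(alleleString(run$result$maternal),
                   alleleString(run$result$paternal))
        ok <- calls != "NC"
        c(correct = sum(calls[ok] == run$truth[ok]), called = sum(ok),
          sw = mean(run$switchError, na.rm = TRUE))
      }, families, countsList)
      rows[[length(rows) + 1L]] <- data.frame(
        level = labels[li], n_samples = sizes[li], rep = r,
        switch_error = mean(outs["sw", ], na.rm = TRUE),
        accuracy = sum(outs["correct", ]) / max(1, sum(outs["called", ])),
        no_call_rate = 1 - sum(outs["called", ]) / (2 * length(families))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a downsampling experiment
#'
#' Accuracy and no-call rate against panel size, one point per replicate.
#'
#' @param df result of [downsampleExperiment()].
#' @return a ggplot object.
#' @export
plotDownsampleExperiment <- function(df) {
  long <- rbind(
    data.frame(n_samples = df$n_samples, rep = df$rep,
               metric = "accuracy", value = df$accuracy),
    data.frame(n_samples = df$n_samples, rep = df$rep,
               metric = "no-call rate", value = df$no_call_rate),
    data.frame(n_samples = df$n_samples, rep = df$rep,
               metric = "switch error", value = df$switch_error)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = n_samples, y = value)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reference panel samples", y = NULL)
}
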