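## Relative haplotype dosage inference: a two-state HMM over informative
## SNPs. Hidden state = which of the decoded parent's haplotypes
## (pathogenic-carrying HAP_P vs normal HAP_N) the fetus inherited.
## Emissions are binomial read counts around the expected plasma alt
## fraction under each hypothesis; transitions allow recombination between
## adjacent sites; decoding is Viterbi with forward-backward posteriors
## feeding a confidence score and the clinical no-call rules.

#' HMM configuration for dosage decoding
#'
#' @param errorRate per-read miscall probability folded into the emission
#'   mean (default 0.005).
#' @param recombRate per-bp transition intensity between adjacent
#'   informative sites (default 1.2e-8; physical distance, no genetic map —
#'   target regions are small enough that map resolution is immaterial).
#' @param csThreshold confidence-score cutoff below which an allele is
#'   reported as no-call (default 0.99).
#' @param minInformative minimum number of informative sites to attempt
#'   decoding (default 1).
#' @param overdispersion optional beta-binomial precision (total
#'   concentration); \code{NULL} (default) keeps plain binomial emissions.
#' @return an \code{"HmmConfig"} list.
#' @export
hmmConfig <- function(errorRate = 0.005, recombRate = 1.2e-8,
                      csThreshold = 0.99, minInformative = 1,
                      overdispersion = NULL) {
  stopifnot(errorRate > 0, errorRate < 1, recombRate > 0,
            csThreshold > 0, csThreshold <= 1, minInformative >= 0)
  structure(list(errorRate = errorRate, recombRate = recombRate,
                 csThreshold = csThreshold, minInformative = minInformative,
                 overdispersion = overdispersion),
            class = "HmmConfig")
}

#' Expected plasma alt-allele fraction under a transmission hypothesis
#'
#' Copy counting over the plasma mixture: the maternal genome contributes
#' weight (1-f)/2 per haplotype and the fetal genome f/2 per haplotype.
#' Writing \code{a_h} for the decoded parent's allele on the hypothesized
#' transmitted haplotype (\code{allele_p} under HAP_P, \code{allele_n}
#' under HAP_N):
#' \itemize{
#'   \item PATERNAL sites (mother homozygous with allele g =
#'     \code{other_allele}): \code{mu = g * (1 - f/2) + (f/2) * a_h};
#'   \item MATERNAL type 1 (father homozygous, allele p =
#'     \code{other_allele}): \code{mu = (1-f)/2 + (f/2) * (a_h + p)};
#'   \item MATERNAL type 2 (father heterozygous, transmitted paternal
#'     allele known from the paternal decode and stored in
#'     \code{other_allele}): same formula as type 1.
#' }
#' At f = 0 the two maternal hypotheses coincide at 1/2: pure maternal
#' plasma carries no transmission signal.
#'
#' @param class \code{"PATERNAL"}, \code{"MATERNAL_T1"} or
#'   \code{"MATERNAL_T2"} (vectorized).
#' @param allele_p,allele_n decoded parent's alleles on the pathogenic and
#'   normal haplotype (must differ: the decoded parent is heterozygous).
#' @param other_allele the fixed contribution (see above).
#' @param hypothesis \code{"HAP_P"} or \code{"HAP_N"}.
#' @param f fetal fraction in [0, 0.5].
#' @return expected alt-read fraction(s) in [0, 1].
#' @export
expectedAltFraction <- function(class, allele_p, allele_n, other_allele,
                                hypothesis, f) {
  stopifnot(f >= 0, f <= 0.5, hypothesis %in% c("HAP_P", "HAP_N"))
  if (any(allele_p + allele_n != 1L)) {
    stop("decoded parent must be heterozygous (allele_p != allele_n)")
  }
  if (!all(class %in% c("PATERNAL", "MATERNAL_T1", "MATERNAL_T2"))) {
    stop("unknown informative-site class")
  }
  a_h <- if (hypothesis == "HAP_P") allele_p else allele_n
  ifelse(class == "PATERNAL",
         other_allele * (1 - f / 2) + (f / 2) * a_h,
         (1 - f) / 2 + (f / 2) * (a_h + other_allele))
}

logEmission <- function(alt, depth, mu, cfg) {
  mu_adj <- mu * (1 - cfg$errorRate) + (1 - mu) * cfg$errorRate
  if (is.null(cfg$overdispersion)) {
    stats::dbinom(alt, depth, mu_adj, log = TRUE)
  } else {
    s <- cfg$overdispersion
    a <- mu_adj * s
    b <- (1 - mu_adj) * s
    lchoose(depth, alt) + lbeta(alt + a, depth - alt + b) - lbeta(a, b)
  }
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Decode fetal inheritance over informative SNPs
#'
#' Two-state Viterbi with forward-backward posteriors, all in log space.
#' State flips between adjacent sites with probability
#' \code{0.5 * (1 - exp(-2 * recombRate * d))} for a gap of \code{d} bp;
#' emissions are binomial (or beta-binomial) read counts with the per-read
#' error rate folded into the mean. Viterbi ties break toward HAP_N
#' (conservative: prefer the normal haplotype when the data cannot decide).
#'
#' @param info informative-site \code{data.frame} from
#'   [selectPaternalInformative()] / [selectMaternalInformative()].
#' @param counts a [CfdnaCounts-class] covering the informative sites.
#' @param f fetal fraction in [0, 0.5].
#' @param cfg an [hmmConfig()].
#' @return an \code{"InheritancePath"} list: \code{states} (per site,
#'   \code{"HAP_P"}/\code{"HAP_N"}), \code{logLik} of the Viterbi path,
#'   \code{posterior} (2 x S forward-backward matrix), \code{postDecoded}
#'   (posterior of the decoded state per site), \code{emissionLog} (2 x S),
#'   and the sites. With zero sites, an empty path (\code{length(states) ==
#'   0}) is returned and downstream confidence is 0.
#' @export
viterbiDecode <- function(info, counts, f, cfg = hmmConfig()) {
  S <- nrow(info)
  if (S == 0 || S < cfg$minInformative) {
    return(structure(list(sites = info, states = character(0),
                          logLik = NA_real_,
                          posterior = matrix(numeric(0), nrow = 2,
                                             dimnames = list(c("HAP_P", "HAP_N"),
                                                             NULL)),
                          postDecoded = numeric(0),
                          emissionLog = matrix(numeric(0), nrow = 2),
                          f = f, cfg = cfg),
                     class = "InheritancePath"))
  }
  if (length(unique(info$chrom)) != 1) {
    stop("informative sites must lie on a single chromosome")
  }
  ord <- order(info$pos)
  info <- info[ord, , drop = FALSE]
  idx <- match(siteKey(info), siteKey(sites(counts)))
  if (anyNA(idx)) {
    stop("plasma counts missing for informative site(s): ",
         paste(utils::head(siteKey(info)[is.na(idx)], 3), collapse = ", "))
  }
  alt <- counts@altDepth[idx]
  depth <- counts@depth[idx]

  emis <- rbind(
    HAP_P = logEmission(alt, depth, expectedAltFraction(
      info$class, info$allele_p, info$allele_n, info$other_allele, "HAP_P", f
    ), cfg),
    HAP_N = logEmission(alt, depth, expectedAltFraction(
      info$class, info$allele_p, info$allele_n, info$other_allele, "HAP_N", f
    ), cfg)
  )
  d <- diff(info$pos)
  pflip <- 0.5 * (1 - exp(-2 * cfg$recombRate * d))
  lflip <- log(pflip)
  lstay <- log1p(-pflip)

  # Viterbi (state 1 = HAP_P, state 2 = HAP_N); >= favors HAP_N on ties
  V <- matrix(-Inf, 2, S)
  ptr <- matrix(1L, 2, S)
  V[, 1] <- log(0.5) + emis[, 1]
  for (j in seq_len(S)[-1]) {
    for (s in 1:2) {
      from_p <- V[1, j - 1] + if (s == 1) lstay[j - 1] else lflip[j - 1]
      from_n <- V[2, j - 1] + if (s == 2) lstay[j - 1] else lflip[j - 1]
      if (from_n >= from_p) {
        V[s, j] <- from_n + emis[s, j]; ptr[s, j] <- 2L
      } else {
        V[s, j] <- from_p + emis[s, j]; ptr[s, j] <- 1L
      }
    }
  }
  states_idx <- integer(S)
  states_idx[S] <- if (V[2, S] >= V[1, S]) 2L else 1L
  for (j in rev(seq_len(S)[-1])) {
    states_idx[j - 1] <- ptr[states_idx[j], j]
  }

  # forward-backward
  fwd <- matrix(-Inf, 2, S)
  bwd <- matrix(0, 2, S)
  fwd[, 1] <- log(0.5) + emis[, 1]
  for (j in seq_len(S)[-1]) {
    for (s in 1:2) {
      fwd[s, j] <- emis[s, j] + logSumExp(c(
        fwd[1, j - 1] + if (s == 1) lstay[j - 1] else lflip[j - 1],
        fwd[2, j - 1] + if (s == 2) lstay[j - 1] else lflip[j - 1]
      ))
    }
  }
  for (j in rev(seq_len(S)[-S])) {
    for (s in 1:2) {
      bwd[s, j] <- logSumExp(c(
        bwd[1, j + 1] + emis[1, j + 1] + if (s == 1) lstay[j] else lflip[j],
        bwd[2, j + 1] + emis[2, j + 1] + if (s == 2) lstay[j] else lflip[j]
      ))
    }
  }
  lpost <- fwd + bwd
  lpost <- sweep(lpost, 2, apply(lpost, 2, logSumExp))
  post <- exp(lpost)
  rownames(post) <- c("HAP_P", "HAP_N")

  structure(list(
    sites = info,
    states = c("HAP_P", "HAP_N")[states_idx],
    logLik = max(V[, S]),
    posterior = post,
    postDecoded = post[cbind(states_idx, seq_len(S))],
    emissionLog = emis,
    f = f, cfg = cfg
  ), class = "InheritancePath")
}

#' @export
print.InheritancePath <- function(x, ...) {
  S <- length(x$states)
  cat(sprintf("InheritancePath: %d informative site%s", S,
              if (S == 1) "" else "s"))
  if (S > 0) {
    cat(sprintf(", %d block%s, logLik %.2f",
                nrow(pathBlocks(x)), if (nrow(pathBlocks(x)) == 1) "" else "s",
                x$logLik))
  }
  cat("\n")
  invisible(x)
}

#' Haplotype blocks of a decoded path
#'
#' Maximal runs of identical Viterbi states. Each block's core genomic
#' interval runs from its first to its last informative site; the extended
#' interval additionally reaches to the midpoint between adjacent blocks
#' (and to +/- Inf at the outer ends), partitioning the chromosome.
#'
#' @param path an \code{"InheritancePath"}.
#' @return \code{data.frame}: \code{state, start_idx, end_idx, chrom,
#'   start_pos, end_pos, ext_start, ext_end}.
#' @export
pathBlocks <- function(path) {
  S <- length(path$states)
  if (S == 0) {
    return(data.frame(state = character(0), start_idx = integer(0),
                      end_idx = integer(0), chrom = character(0),
                      start_pos = numeric(0), end_pos = numeric(0),
                      ext_start = numeric(0), ext_end = numeric(0)))
  }
  r <- rle(path$states)
  end_idx <- cumsum(r$lengths)
  start_idx <- c(1L, utils::head(end_idx, -1) + 1L)
  start_pos <- path$sites$pos[start_idx]
  end_pos <- path$sites$pos[end_idx]
  n <- length(start_idx)
  ext_start <- c(-Inf, (path$sites$pos[start_idx[-1]] +
                          path$sites$pos[end_idx[-n]]) / 2)
  ext_end <- c(ext_start[-1], Inf)
  data.frame(state = r$values, start_idx = start_idx, end_idx = end_idx,
             chrom = path$sites$chrom[start_idx],
             start_pos = as.numeric(start_pos), end_pos = as.numeric(end_pos),
             ext_start = ext_start, ext_end = ext_end,
             stringsAsFactors = FALSE)
}

## Which block carries the call for this target: the block whose core
## site interval contains the target midpoint; a single block always
## qualifies (one inherited segment covers the region). NA when >= 2
## blocks exist and none spans the target (the no-call rule's case 2).
spanningBlockIndex <- function(blocks, target) {
  if (nrow(blocks) == 0) return(NA_integer_)
  mid <- targetMidpoint(target)
  hit <- which(blocks$chrom == target$chrom &
                 blocks$start_pos <= mid & blocks$end_pos >= mid)
  if (length(hit) > 0) return(hit[1])
  if (nrow(blocks) == 1) return(1L)
  NA_integer_
}

#' Confidence score of a decoded inheritance call
#'
#' The forward-backward posterior probability of the decoded state at the
#' informative site nearest the target locus within the spanning block
#' (anchoring at the target rather than averaging over the block: the score
#' is the probability that the call at the target is correct). With no
#' spanning block the anchor falls back to the globally nearest informative
#' site; with zero informative sites the score is 0.
#'
#' @param path an \code{"InheritancePath"}.
#' @param blocks block table from [pathBlocks()].
#' @param target a \code{TargetGene}.
#' @return confidence score in [0, 1].
#' @export
confidenceScore <- function(path, blocks, target) {
  S <- length(path$states)
  if (S == 0) return(0)
  mid <- targetMidpoint(target)
  bi <- spanningBlockIndex(blocks, target)
  cand <- if (is.na(bi)) seq_len(S) else blocks$start_idx[bi]:blocks$end_idx[bi]
  anchor <- cand[which.min(abs(path$sites$pos[cand] - mid))]
  path$postDecoded[anchor]
}

#' Turn a decoded path into a clinical allele call
#'
#' No-call when (1) the confidence score is below \code{cfg$csThreshold},
#' or (2) the path holds two or more blocks and none spans the target.
#' Otherwise the call is the state of the spanning block: pathogenic
#' (reporting the parent's flagged variant id) or normal. Supporting-SNP
#' counts tally, per informative site, which hypothesis has the higher
#' individual emission likelihood (ties support neither).
#'
#' @param path an \code{"InheritancePath"}.
#' @param blocks block table from [pathBlocks()].
#' @param cs confidence score from [confidenceScore()].
#' @param target a \code{TargetGene}.
#' @param cfg an [hmmConfig()].
#' @param parent \code{"maternal"} or \code{"paternal"}.
#' @param variantId variant id carried on the decoded parent's pathogenic
#'   haplotype (reported when the call is pathogenic).
#' @return an \code{"AlleleCall"} list: \code{parent, call, variantId, cs,
#'   nSnpsHapP, nSnpsHapN, flags}.
#' @export
callAllele <- function(path, blocks, cs, target, cfg = hmmConfig(),
                       parent = "maternal", variantId = NA_character_) {
  n_p <- sum(path$emissionLog[1, ] > path$emissionLog[2, ])
  n_n <- sum(path$emissionLog[2, ] > path$emissionLog[1, ])
  bi <- spanningBlockIndex(blocks, target)
  no_call <- cs < cfg$csThreshold || (nrow(blocks) >= 2 && is.na(bi))
  call <- if (no_call) {
    "no_call"
  } else if (blocks$state[bi] == "HAP_P") "pathogenic" else "normal"
  structure(list(
    parent = parent, call = call,
    variantId = if (identical(call, "pathogenic")) variantId else NA_character_,
    cs = cs, nSnpsHapP = n_p, nSnpsHapN = n_n, flags = character(0)
  ), class = "AlleleCall")
}

#' @export
print.AlleleCall <- function(x, ...) {
  lbl <- switch(x$call, pathogenic = x$variantId, normal = "N",
                no_call = "NC")
  cat(sprintf("%s allele: %s (CS %.4f; SNPs %d/%d for HAP_P/HAP_N%s)\n",
              x$parent, lbl, x$cs, x$nSnpsHapP, x$nSnpsHapN,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Resolved blocks of a paternal decode
#'
#' Blocks whose decoded state is trusted enough to gate type-2 maternal
#' site selection: every site in the block must carry a forward-backward
#' posterior of the decoded state at or above the confidence threshold.
#' Partial blocks qualify; resolution is per block, not per whole path.
#'
#' @param path an \code{"InheritancePath"} from the paternal decode.
#' @param cfg an [hmmConfig()].
#' @return block table (subset of [pathBlocks()] rows).
#' @export
resolvedBlocks <- function(path, cfg = hmmConfig()) {
  blocks <- pathBlocks(path)
  if (nrow(blocks) == 0) return(blocks)
  ok <- vapply(seq_len(nrow(blocks)), function(b) {
    span <- blocks$start_idx[b]:blocks$end_idx[b]
    min(path$postDecoded[span]) >= cfg$csThreshold
  }, logical(1))
  blocks[ok, , drop = FALSE]
}

forcedCall <- function(parent, call, variantId, flag) {
  structure(list(parent = parent, call = call,
                 variantId = variantId, cs = 1,
                 nSnpsHapP = 0L, nSnpsHapN = 0L, flags = flag),
            class = "AlleleCall")
}

targetVariantOnHap <- function(parentHaps, target, hapP) {
  ids <- intersect(pathogenicFlags(parentHaps)[[paste0("hap", hapP)]],
                   target$pathogenicSites$id)
  if (length(ids) == 0) NA_character_ else paste(ids, collapse = ",")
}

decodeOneParent <- function(parentLabel, info, counts, f, cfg, target,
                            variantId) {
  path <- viterbiDecode(info, counts, f, cfg)
  blocks <- pathBlocks(path)
  cs <- confidenceScore(path, blocks, target)
  call <- callAllele(path, blocks, cs, target, cfg, parentLabel, variantId)
  list(call = call, path = path, blocks = blocks)
}

#' Infer fetal inheritance for both parental alleles
#'
#' The full two-step procedure per target gene: decode paternal
#' transmission on paternal informative SNPs first; its resolved blocks
#' unlock type-2 maternal sites; then decode maternal transmission on
#' type-1 + type-2 sites. SNPs inside any parental CNV region are excluded
#' from both steps. A parent who is not a simple heterozygous carrier at
#' the target needs no decoding: homozygous-pathogenic forces a pathogenic
#' call and a non-carrier forces a normal call, both with confidence 1 and
#' flagged \code{"uninformative-by-genotype"}.
#'
#' @param father,mother phased [ParentalHaplotypes-class] over one shared
#'   site list.
#' @param counts a [CfdnaCounts-class] with the fetal fraction estimated
#'   (see [estimateFetalFraction()]), or supply \code{f} explicitly.
#' @param targets list of \code{TargetGene} (or a single one).
#' @param cfg an [hmmConfig()].
#' @param f fetal fraction override; default taken from \code{counts}.
#' @return named list per target: \code{paternal} and \code{maternal}
#'   \code{"AlleleCall"}s plus \code{ff} and the decode audit
#'   (\code{paternalPath}, \code{maternalPath}, block tables).
#' @export
inferFetus <- function(father, mother, counts, targets, cfg = hmmConfig(),
                       f = NULL) {
  if (inherits(targets, "TargetGene")) targets <- list(targets)
  if (is.null(f)) f <- fetalFraction(counts)
  if (is.na(f)) {
    stop("fetal fraction not estimated; run estimateFetalFraction() or pass f")
  }
  cnv <- parentalCnvRegions(father, mother)
  out <- lapply(targets, function(target) {
    hp_f <- pathogenicHapIndex(father, target)
    hp_m <- pathogenicHapIndex(mother, target)

    pat_blocks_resolved <- NULL
    if (identical(hp_f, "hom")) {
      id <- targetVariantOnHap(father, target, 1L)
      pat <- list(call = forcedCall("paternal", "pathogenic", id,
                                    "uninformative-by-genotype"),
                  path = NULL, blocks = NULL)
    } else if (identical(hp_f, "none")) {
      pat <- list(call = forcedCall("paternal", "normal", NA_character_,
                                    "uninformative-by-genotype"),
                  path = NULL, blocks = NULL)
    } else {
      info_p <- selectPaternalInformative(father, mother, target,
                                          cnvRegions = cnv, hapP = hp_f)
      pat <- decodeOneParent("paternal", info_p, counts, f, cfg, target,
                             targetVariantOnHap(father, target, hp_f))
      pat_blocks_resolved <- resolvedBlocks(pat$path, cfg)
    }

    if (identical(hp_m, "hom")) {
      id <- targetVariantOnHap(mother, target, 1L)
      mat <- list(call = forcedCall("maternal", "pathogenic", id,
                                    "uninformative-by-genotype"),
                  path = NULL, blocks = NULL)
    } else if (identical(hp_m, "none")) {
      mat <- list(call = forcedCall("maternal", "normal", NA_character_,
                                    "uninformative-by-genotype"),
                  path = NULL, blocks = NULL)
    } else {
      info_m <- selectMaternalInformative(father, mother, target,
                                          paternalBlocks = pat_blocks_resolved,
                                          cnvRegions = cnv, hapP = hp_m)
      mat <- decodeOneParent("maternal", info_m, counts, f, cfg, target,
                             targetVariantOnHap(mother, target, hp_m))
    }

    list(paternal = pat$call, maternal = mat$call, ff = f,
         paternalPath = pat$path, maternalPath = mat$path,
         paternalBlocks = pat$blocks, maternalBlocks = mat$blocks)
  })
  names(out) <- vapply(targets, function(t) t$name, character(1))
  out
}
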