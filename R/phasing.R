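## Parental phasing: population-based haplotyping against a phased panel
## (diploid haplotype-copying model, Viterbi-decoded in C++), family-based
## trio phasing as comparator, and concordance / switch-error metrics.

#' Phase a parent against a phased reference panel
#'
#' Population-based haplotyping: the parent's unphased genotypes are
#' explained as a mosaic of two panel haplotypes under a diploid
#' haplotype-copying model. The hidden state is the ordered pair of panel
#' haplotypes being copied; each chromosome of the pair switches to a
#' uniformly chosen haplotype with probability \code{1 - exp(-rho * d)} per
#' interval of \code{d} bp, where \code{rho = 4 * nE * 1e-8 / H}; emissions
#' compare implied to observed genotype dosage with a per-allele
#' \code{mismatchRate}. The maximum-a-posteriori pair sequence (joint
#' Viterbi over ordered pairs, ties toward the smaller haplotype index)
#' assigns phase at heterozygous sites. The result is genotype-consistent
#' at every site by construction: homozygous sites are forced, and at a
#' heterozygous site where the decoded pair is uninformative (both copied
#' haplotypes carry the same allele) the first haplotype's allele is kept
#' for hap1 and the complement assigned to hap2.
#'
#' @param genotypes one sample's genotype \code{data.frame} as returned by
#'   [readGenotypeTable()] (site columns + \code{allele_a}, \code{allele_b}).
#' @param panel a [PhasedPanel-class]; genotype sites must all be present in
#'   the panel.
#' @param nE effective population size scaling the recombination intensity.
#' @param mismatchRate per-allele copying mismatch probability.
#' @param maxPanelHaps conditioning-haplotype cap: when the panel holds more
#'   haplotypes, the decoder restricts the state space to the
#'   \code{maxPanelHaps} panel haplotypes most compatible with the sample's
#'   genotypes (fewest impossible alleles at homozygous sites) — the usual
#'   composite-reference device of large-panel phasers. \code{Inf} disables
#'   the cap.
#' @return a [ParentalHaplotypes-class] with \code{source = "PBH"}. The
#'   decoded panel-haplotype copy path is attached as attribute
#'   \code{"copyPath"} (indices into the possibly restricted panel).
#' @export
phaseWithPanel <- function(genotypes, panel, nE = 1e4, mismatchRate = 0.005,
                           maxPanelHaps = 400L) {
  stopifnot(is(panel, "PhasedPanel"))
  H <- nHaplotypes(panel)
  if (H < 2) stop("empty or degenerate panel (need >= 2 haplotypes)")
  pkey <- siteKey(sites(panel))
  gkey <- siteKey(genotypes)
  idx <- match(gkey, pkey)
  if (anyNA(idx)) {
    stop("genotype site(s) absent from the panel: ",
         paste(utils::head(gkey[is.na(idx)], 3), collapse = ", "))
  }
  g <- genotypes$allele_a + genotypes$allele_b
  panelHaps <- haplotypes(panel)[, idx, drop = FALSE]
  if (H > maxPanelHaps) {
    hom <- which(!is.na(g) & g != 1L)
    mism <- panelHaps[, hom, drop = FALSE] -
      rep(g[hom] / 2, each = H)
    keep <- sort(order(rowSums(abs(mism)))[seq_len(maxPanelHaps)])
    panelHaps <- panelHaps[keep, , drop = FALSE]
    H <- nrow(panelHaps)
  }
  S <- nrow(genotypes)
  hap1 <- hap2 <- integer(S)
  copy_path <- matrix(NA_integer_, S, 2)
  for (chr in unique(genotypes$chrom)) {
    sel <- which(genotypes$chrom == chr)
    res <- diploid_viterbi_cpp(
      panelHaps[, sel, drop = FALSE],
      as.integer(g[sel]),
      as.numeric(genotypes$pos[sel]),
      rho = 4 * nE * 1e-8 / H, lambda = mismatchRate
    )
    copy_path[sel, ] <- res$path
    hx <- panelHaps[cbind(res$path[, 1], sel)]
    gs <- g[sel]
    hap1[sel] <- ifelse(gs == 1L, hx, gs %/% 2L)
    hap2[sel] <- ifelse(gs == 1L, 1L - hx, gs %/% 2L)
  }
  # missing genotypes carry no phase information
  hap1[is.na(g)] <- NA_integer_
  hap2[is.na(g)] <- NA_integer_
  out <- ParentalHaplotypes(genotypes[, SITE_COLS], hap1, hap2, source = "PBH")
  attr(out, "copyPath") <- copy_path
  out
}

## Log-probability of one copying-pair path (initial uniform prior over
## pairs dropped, matching the C++ scorer). Used by the decoder's tests as
## the shared path-scoring convention.
scorePairPath <- function(haps, g, pos, rho, lambda, path) {
  H <- nrow(haps)
  S <- length(g)
  emit <- function(j, x, y) {
    if (is.na(g[j])) return(0)
    m <- abs(haps[x, j] + haps[y, j] - g[j])
    m * log(lambda) + (2 - m) * log(1 - lambda)
  }
  ltrans <- function(d, from, to) {
    r <- -expm1(-rho * d)
    log((1 - r) * (from == to) + r / H)
  }
  lp <- emit(1, path[1, 1], path[1, 2])
  for (j in seq_len(S)[-1]) {
    d <- pos[j] - pos[j - 1]
    lp <- lp + ltrans(d, path[j - 1, 1], path[j, 1]) +
      ltrans(d, path[j - 1, 2], path[j, 2]) +
      emit(j, path[j, 1], path[j, 2])
  }
  lp
}

#' Phase parents through an offspring (family-based haplotyping)
#'
#' Mendelian transmission fixes phase wherever it is unambiguous: a
#' homozygous child pins the transmitted allele of every heterozygous
#' parent; a heterozygous child with one homozygous parent pins the other
#' parent's transmitted allele. Sites heterozygous in all three members are
#' left unphased; Mendelian-inconsistent sites are flagged and excluded
#' (unphased in both parents). hap1 carries the transmitted allele.
#'
#' @param fatherGt,motherGt,childGt genotype \code{data.frame}s over one
#'   shared site list.
#' @return list with elements \code{father}, \code{mother} (both
#'   [ParentalHaplotypes-class], \code{source = "FBH"}) and
#'   \code{inconsistent} (logical per site).
#' @export
phaseTrio <- function(fatherGt, motherGt, childGt) {
  if (!sameSites(fatherGt, motherGt) || !sameSites(fatherGt, childGt)) {
    stop("father, mother and child must share one site list")
  }
  gF <- fatherGt$allele_a + fatherGt$allele_b
  gM <- motherGt$allele_a + motherGt$allele_b
  gC <- childGt$allele_a + childGt$allele_b
  S <- length(gF)
  f1 <- f2 <- m1 <- m2 <- rep(NA_integer_, S)
  inconsistent <- logical(S)
  can_give <- function(g, a) !is.na(g) & (g == 2L * a | g == 1L)
  for (i in seq_len(S)) {
    if (is.na(gC[i]) || is.na(gF[i]) || is.na(gM[i])) {
      # no trio information; homozygous parents are still trivially phased
      if (!is.na(gF[i]) && gF[i] != 1L) f1[i] <- f2[i] <- gF[i] %/% 2L
      if (!is.na(gM[i]) && gM[i] != 1L) m1[i] <- m2[i] <- gM[i] %/% 2L
      next
    }
    ok <- switch(as.character(gC[i]),
      "0" = can_give(gF[i], 0L) && can_give(gM[i], 0L),
      "2" = can_give(gF[i], 1L) && can_give(gM[i], 1L),
      "1" = (can_give(gF[i], 0L) && can_give(gM[i], 1L)) ||
            (can_give(gF[i], 1L) && can_give(gM[i], 0L))
    )
    if (!ok) {
      inconsistent[i] <- TRUE
      next
    }
    tF <- tM <- NA_integer_
    if (gC[i] == 0L) { tF <- 0L; tM <- 0L }
    else if (gC[i] == 2L) { tF <- 1L; tM <- 1L }
    else { # child het: one parent homozygous resolves both transmissions
      if (gF[i] != 1L) { tF <- gF[i] %/% 2L; tM <- 1L - tF }
      else if (gM[i] != 1L) { tM <- gM[i] %/% 2L; tF <- 1L - tM }
    }
    if (gF[i] != 1L) { f1[i] <- f2[i] <- gF[i] %/% 2L }
    else if (!is.na(tF)) { f1[i] <- tF; f2[i] <- 1L - tF }
    if (gM[i] != 1L) { m1[i] <- m2[i] <- gM[i] %/% 2L }
    else if (!is.na(tM)) { m1[i] <- tM; m2[i] <- 1L - tM }
  }
  list(
    father = ParentalHaplotypes(fatherGt[, SITE_COLS], f1, f2, source = "FBH"),
    mother = ParentalHaplotypes(motherGt[, SITE_COLS], m1, m2, source = "FBH"),
    inconsistent = inconsistent
  )
}

commonPhasedHet <- function(a, b) {
  if (!sameSites(sites(a), sites(b))) stop("haplotype site lists differ")
  gt_a <- a@hap1 + a@hap2
  gt_b <- b@hap1 + b@hap2
  which(!is.na(gt_a) & !is.na(gt_b) & gt_a == 1L & gt_b == 1L)
}

#' Concordance between two phasings of the same parent
#'
#' Compares the two phasings over sites heterozygous and phased in both,
#' after choosing the haplotype orientation (identity or global hap1/hap2
#' swap of the second argument) that maximizes agreement. Symmetric and
#' invariant to global relabeling of either argument.
#'
#' @param a,b [ParentalHaplotypes-class] over the same site list.
#' @return proportion of commonly phased heterozygous sites with identical
#'   allele assignment, in [0, 1].
#' @export
haplotypeConcordance <- function(a, b) {
  idx <- commonPhasedHet(a, b)
  if (length(idx) == 0) stop("no commonly phased heterozygous sites")
  agree <- sum(a@hap1[idx] == b@hap1[idx])
  max(agree, length(idx) - agree) / length(idx)
}

#' Switch-error rate of a phasing against the truth
#'
#' Over commonly phased heterozygous sites in genomic order, counts
#' orientation changes between consecutive sites (a "switch") relative to
#' the true phase, divided by the number of consecutive pairs.
#'
#' @param a candidate [ParentalHaplotypes-class].
#' @param truth reference phasing over the same site list.
#' @return switch-error proportion in [0, 1]; \code{NA} when fewer than two
#'   commonly phased heterozygous sites exist.
#' @export
switchErrorRate <- function(a, truth) {
  idx <- commonPhasedHet(a, truth)
  if (length(idx) < 2) return(NA_real_)
  ord <- idx[order(sites(a)$chrom[idx], sites(a)$pos[idx])]
  rel <- a@hap1[ord] == truth@hap1[ord]
  sum(rel[-1] != rel[-length(rel)]) / (length(rel) - 1)
}
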