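## Reference-panel construction: site quality filters over a carrier-
## screening cohort, the CNV-as-pseudo-SNP encoding, and assembly of the
## phased panel with per-haplotype pathogenic flags.

#' Bundle cohort-level genotype and depth matrices
#'
#' @param sites site table (S sites).
#' @param depth,altDepth N x S integer matrices of total / alt read counts.
#' @param genotype N x S matrix coded 0 (hom-ref), 1 (het), 2 (hom-alt),
#'   NA (missing).
#' @param samples sample ids (defaults to rownames of \code{genotype}).
#' @return a \code{"CohortMatrix"} list.
#' @export
cohortMatrix <- function(sites, depth, altDepth, genotype, samples = NULL) {
  validateSites(sites)
  stopifnot(
    nrow(depth) == nrow(genotype), ncol(depth) == nrow(sites),
    all(dim(depth) == dim(altDepth)), ncol(genotype) == nrow(sites)
  )
  if (any(altDepth > depth, na.rm = TRUE)) {
    stop("altDepth exceeds depth")
  }
  if (is.null(samples)) {
    samples <- rownames(genotype) %||% paste0("S", seq_len(nrow(genotype)))
  }
  structure(list(sites = sites, samples = samples, depth = depth,
                 altDepth = altDepth, genotype = genotype),
            class = "CohortMatrix")
}

#' Filter panel SNPs by depth and heterozygous allele-ratio skew
#'
#' A site is removed when either rule fires (the rules are independent and
#' combined by OR):
#' \itemize{
#'   \item depth rule: the fraction of cohort samples (missing genotypes
#'     included in the denominator) with depth below \code{depthMin} exceeds
#'     \code{lowDepthFrac};
#'   \item skew rule: among heterozygous samples, the fraction whose
#'     alt-allele ratio \code{alt_depth/depth} lies in the closed band
#'     \code{[ratioLo, ratioHi]} exceeds \code{skewFrac}.
#' }
#' Both comparisons are strict (\code{>}). Sites with no heterozygous
#' samples are never removed by the skew rule, and CNV pseudo-sites are
#' exempt from it (read-depth ratios are meaningless across a large
#' deletion). Defaults: depth < 20x in more than 2\% of the cohort, or an
#' allele ratio within 5--40\% in more than 70\% of heterozygotes.
#'
#' @param cohort a [cohortMatrix()].
#' @param depthMin minimum acceptable per-sample depth (reads).
#' @param lowDepthFrac tolerated fraction of low-depth samples.
#' @param ratioLo,ratioHi closed skew band for the heterozygous alt ratio.
#' @param skewFrac tolerated fraction of skewed heterozygotes.
#' @return the retained subset of \code{cohort$sites}, order preserved.
#' @export
filterPanelSnps <- function(cohort, depthMin = 20, lowDepthFrac = 0.02,
                            ratioLo = 0.05, ratioHi = 0.40, skewFrac = 0.70) {
  stopifnot(inherits(cohort, "CohortMatrix"))
  if (nrow(cohort$genotype) == 0 || nrow(cohort$sites) == 0) {
    stop("empty cohort")
  }
  fracs <- c(lowDepthFrac, ratioLo, ratioHi, skewFrac)
  if (any(fracs < 0 | fracs > 1)) stop("threshold proportions must be in [0, 1]")
  n <- nrow(cohort$genotype)
  low_frac <- colSums(cohort$depth < depthMin) / n
  remove_depth <- low_frac > lowDepthFrac

  remove_skew <- vapply(seq_len(nrow(cohort$sites)), function(j) {
    if (cohort$sites$kind[j] == "CNV") return(FALSE)
    het <- which(!is.na(cohort$genotype[, j]) & cohort$genotype[, j] == 1L &
                   cohort$depth[, j] > 0)
    if (length(het) == 0) return(FALSE)
    ratio <- cohort$altDepth[het, j] / cohort$depth[het, j]
    mean(ratio >= ratioLo & ratio <= ratioHi) > skewFrac
  }, logical(1))

  keep <- !(remove_depth | remove_skew)
  out <- cohort$sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Encode a CNV call as a pseudo-SNP genotype
#'
#' CNVs enter the phasing machinery disguised as biallelic sites: the
#' genomic position is the CNV start, genotype "0/1" means a heterozygous
#' and "1/1" a homozygous CNV.
#'
#' @param chrom chromosome of the CNV.
#' @param start,end 1-based inclusive CNV coordinates.
#' @param copyState \code{"het"} or \code{"hom"} (deletion or duplication
#'   carried on one or both haplotypes).
#' @param id variant id (e.g. \code{"--SEA"}).
#' @return one-row genotype \code{data.frame} (site columns plus
#'   \code{allele_a, allele_b, phased, depth, alt_depth}).
#' @export
encodeCnvAsSnp <- function(chrom, start, end, copyState, id = NA_character_) {
  if (!copyState %in% c("het", "hom")) {
    stop("unknown copy state '", copyState, "' (expected het or hom)")
  }
  st <- siteTable(chrom, start, ref = "N", alt = "<CNV>", kind = "CNV",
                  cnv_end = end, id = id)
  cbind(st, data.frame(
    allele_a = if (copyState == "hom") 1L else 0L,
    allele_b = 1L, phased = FALSE, depth = 0L, alt_depth = 0L
  ))
}

#' Decode a CNV pseudo-SNP genotype back to a copy state
#'
#' Inverse of [encodeCnvAsSnp()] on valid copy states.
#'
#' @param genotypeRow one-row genotype data.frame with \code{kind == "CNV"}.
#' @return list with \code{chrom, start, end, copyState, id}.
#' @export
decodeCnvPseudoSnp <- function(genotypeRow) {
  stopifnot(nrow(genotypeRow) == 1, genotypeRow$kind == "CNV")
  dosage <- genotypeRow$allele_a + genotypeRow$allele_b
  if (is.na(dosage) || !dosage %in% 1:2) {
    stop("CNV pseudo-SNP genotype must be 0/1 or 1/1")
  }
  list(chrom = genotypeRow$chrom, start = genotypeRow$pos,
       end = genotypeRow$cnv_end,
       copyState = if (dosage == 2L) "hom" else "het",
       id = genotypeRow$id)
}

#' Assemble a phased reference panel from phased samples
#'
#' Stacks two haplotype rows per sample over one shared (filtered) site
#' list and flags each haplotype with the pathogenic variant ids whose alt
#' allele it carries.
#'
#' @param phasedSamples named list of [ParentalHaplotypes-class], all over
#'   the same site list, fully phased.
#' @param pathogenicVariants optional site table restricting which ids are
#'   flagged; default: every id-bearing site in the shared site list.
#' @return a [PhasedPanel-class] with \code{2 * length(phasedSamples)} rows.
#' @export
buildReferencePanel <- function(phasedSamples, pathogenicVariants = NULL) {
  stopifnot(length(phasedSamples) > 0)
  ref_sites <- sites(phasedSamples[[1]])
  for (s in names(phasedSamples) %||% seq_along(phasedSamples)) {
    if (!sameSites(sites(phasedSamples[[s]]), ref_sites)) {
      stop("sample '", s, "' has a different site list")
    }
  }
  if (!is.null(pathogenicVariants)) {
    keep_ids <- pathogenicVariants$id
    ref_sites$id[!ref_sites$id %in% keep_ids] <- NA_character_
  }
  H <- 2L * length(phasedSamples)
  haps <- matrix(0L, nrow = H, ncol = nrow(ref_sites))
  for (i in seq_along(phasedSamples)) {
    h <- phasedSamples[[i]]
    if (anyNA(h@hap1)) {
      stop("panel samples must be fully phased (sample ",
           names(phasedSamples)[i] %||% i, " has unphased sites)")
    }
    haps[2L * i - 1L, ] <- h@hap1
    haps[2L * i, ] <- h@hap2
  }
  rownames(haps) <- paste0(rep(names(phasedSamples) %||%
                                 paste0("S", seq_along(phasedSamples)),
                               each = 2), c("_h1", "_h2"))
  PhasedPanel(ref_sites, haps)
}

#' Allele frequencies of a phased panel
#'
#' @param panel a [PhasedPanel-class].
#' @return numeric vector: per-site alt-allele frequency (column means of
#'   the haplotype matrix).
#' @export
panelAlleleFreq <- function(panel) {
  colMeans(haplotypes(panel))
}
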