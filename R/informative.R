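## Informative-SNP selection, in the two-step order the dosage decoder
## expects: paternal-only-heterozygous sites first; maternal sites second,
## where type 2 (double-heterozygous) sites become usable only inside
## genomic blocks whose paternal transmission the first step resolved.

#' Genomic regions covered by a parental CNV
#'
#' The \code{[pos, cnv_end]} interval of every CNV pseudo-site carried (alt
#' allele on at least one haplotype) by either parent. Plasma allele ratios
#' inside a deletion are distorted regardless of which parent carries it,
#' so sites in these regions are excluded from informative selection for
#' both parents.
#'
#' @param ... one or more [ParentalHaplotypes-class] objects.
#' @return a \code{GRanges} (possibly empty) of CNV regions.
#' @export
parentalCnvRegions <- function(...) {
  parents <- list(...)
  grl <- lapply(parents, function(p) {
    st <- sites(p)
    dosage <- p@hap1 + p@hap2
    carried <- st$kind == "CNV" & !is.na(dosage) & dosage >= 1L
    sitesToGRanges(st[carried, , drop = FALSE])
  })
  out <- do.call(c, grl)
  GenomicRanges::reduce(out)
}

inCnvRegion <- function(st, cnvRegions) {
  if (is.null(cnvRegions) || length(cnvRegions) == 0) {
    return(logical(nrow(st)))
  }
  IRanges::overlapsAny(sitesToGRanges(st), cnvRegions)
}

## Identify which haplotype carries the target's pathogenic variant.
## Returns 1 or 2 for a simple heterozygous carrier, "hom" when both
## haplotypes carry one, "none" when neither does.
pathogenicHapIndex <- function(parent, target) {
  ids <- target$pathogenicSites$id
  on1 <- any(pathogenicFlags(parent)$hap1 %in% ids)
  on2 <- any(pathogenicFlags(parent)$hap2 %in% ids)
  if (on1 && on2) "hom" else if (on1) 1L else if (on2) 2L else "none"
}

informativeFrame <- function(st, class, allele_p, allele_n, other_allele) {
  cbind(st, data.frame(
    class = rep(class, length.out = nrow(st)),
    allele_p = as.integer(allele_p),
    allele_n = as.integer(allele_n), other_allele = as.integer(other_allele),
    stringsAsFactors = FALSE
  ))
}

#' Select paternal informative SNPs
#'
#' Sites heterozygous in the father but homozygous in the mother, excluding
#' CNV pseudo-sites, CNV-region sites, sites off the target's chromosome
#' (dosage signal requires linkage to the target), and sites with a missing
#' or unphased genotype in either parent. Each site is annotated with the father's
#' allele on his pathogenic (\code{allele_p}) and normal (\code{allele_n})
#' haplotype and the mother's homozygous allele (\code{other_allele}).
#'
#' @param father,mother [ParentalHaplotypes-class] over one shared site list.
#' @param target a \code{TargetGene}; defines which paternal haplotype is
#'   "pathogenic".
#' @param cnvRegions \code{GRanges} of excluded regions; default: regions of
#'   CNVs carried by either parent.
#' @param hapP which paternal haplotype (1 or 2) carries the target variant;
#'   auto-detected from the pathogenic labels when \code{NULL}.
#' @return \code{data.frame} of informative sites (class \code{"PATERNAL"}).
#' @export
selectPaternalInformative <- function(father, mother, target,
                                      cnvRegions = NULL, hapP = NULL) {
  if (!sameSites(sites(father), sites(mother))) {
    stop("father and mother must share one site list")
  }
  if (is.null(cnvRegions)) cnvRegions <- parentalCnvRegions(father, mother)
  if (is.null(hapP)) {
    hapP <- pathogenicHapIndex(father, target)
    if (!hapP %in% c(1L, 2L)) {
      stop("father is not a simple heterozygous carrier for ", target$name,
           " (", hapP, "); the caller must handle forced calls")
    }
  }
  st <- sites(father)
  gF <- father@hap1 + father@hap2
  gM <- mother@hap1 + mother@hap2
  keep <- !is.na(gF) & !is.na(gM) & gF == 1L & gM != 1L &
    st$chrom == target$chrom &
    st$kind != "CNV" & !inCnvRegion(st, cnvRegions)
  idx <- which(keep)
  hp <- if (hapP == 1L) father@hap1 else father@hap2
  hn <- if (hapP == 1L) father@hap2 else father@hap1
  informativeFrame(
    `rownames<-`(st[idx, , drop = FALSE], NULL), "PATERNAL",
    hp[idx], hn[idx], gM[idx] %/% 2L
  )
}

#' Select maternal informative SNPs
#'
#' Two classes: type 1 sites are heterozygous in the mother and homozygous
#' in the father; type 2 sites are heterozygous in both parents but lie in
#' a genomic block whose paternal transmission was already resolved, so the
#' transmitted paternal allele is known and recorded as
#' \code{other_allele}. CNV pseudo-sites, CNV-region sites, off-chromosome
#' sites, and sites with missing or unphased parental genotypes are
#' excluded.
#'
#' @param father,mother [ParentalHaplotypes-class] over one shared site list.
#' @param target a \code{TargetGene}; defines which maternal haplotype is
#'   "pathogenic".
#' @param paternalBlocks \code{data.frame} of resolved paternal blocks
#'   (columns \code{state, ext_start, ext_end, chrom}; see
#'   [resolvedBlocks()]), or \code{NULL} when paternal decoding produced
#'   none.
#' @param cnvRegions \code{GRanges} of excluded regions; default: regions of
#'   CNVs carried by either parent.
#' @param hapP which maternal haplotype (1 or 2) carries the target variant;
#'   auto-detected when \code{NULL}.
#' @return \code{data.frame} of informative sites (classes
#'   \code{"MATERNAL_T1"}, \code{"MATERNAL_T2"}).
#' @export
selectMaternalInformative <- function(father, mother, target,
                                      paternalBlocks = NULL,
                                      cnvRegions = NULL, hapP = NULL) {
  if (!sameSites(sites(father), sites(mother))) {
    stop("father and mother must share one site list")
  }
  if (is.null(cnvRegions)) cnvRegions <- parentalCnvRegions(father, mother)
  if (is.null(hapP)) {
    hapP <- pathogenicHapIndex(mother, target)
    if (!hapP %in% c(1L, 2L)) {
      stop("mother is not a simple heterozygous carrier for ", target$name,
           " (", hapP, "); the caller must handle forced calls")
    }
  }
  st <- sites(mother)
  gF <- father@hap1 + father@hap2
  gM <- mother@hap1 + mother@hap2
  usable <- !is.na(gF) & !is.na(gM) & gM == 1L &
    st$chrom == target$chrom &
    st$kind != "CNV" & !inCnvRegion(st, cnvRegions)
  hp <- if (hapP == 1L) mother@hap1 else mother@hap2
  hn <- if (hapP == 1L) mother@hap2 else mother@hap1

  t1 <- which(usable & gF != 1L)
  out1 <- informativeFrame(
    `rownames<-`(st[t1, , drop = FALSE], NULL), "MATERNAL_T1",
    hp[t1], hn[t1], gF[t1] %/% 2L
  )

  t2 <- integer(0)
  pat_allele <- integer(0)
  if (!is.null(paternalBlocks) && nrow(paternalBlocks) > 0) {
    cand <- which(usable & gF == 1L)
    if (length(cand) > 0) {
      blk <- vapply(cand, function(i) {
        hit <- which(paternalBlocks$chrom == st$chrom[i] &
                       paternalBlocks$ext_start <= st$pos[i] &
                       paternalBlocks$ext_end >= st$pos[i])
        if (length(hit) == 0) NA_integer_ else hit[1]
      }, integer(1))
      t2 <- cand[!is.na(blk)]
      blk <- blk[!is.na(blk)]
      if (length(t2) > 0) {
        # transmitted paternal allele = father's allele on the haplotype
        # named by the resolved block state at this site
        pat_hp <- pathogenicHapIndex(father, target)
        fh_p <- if (identical(pat_hp, 2L)) father@hap2 else father@hap1
        fh_n <- if (identical(pat_hp, 2L)) father@hap1 else father@hap2
        pat_allele <- ifelse(paternalBlocks$state[blk] == "HAP_P",
                             fh_p[t2], fh_n[t2])
      }
    }
  }
  out2 <- informativeFrame(
    `rownames<-`(st[t2, , drop = FALSE], NULL),
    if (length(t2)) "MATERNAL_T2" else character(0),
    hp[t2], hn[t2], pat_allele
  )
  out <- rbind(out1, out2)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
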