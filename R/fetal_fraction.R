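## Fetal fraction from paternal-specific alleles: at sites where the mother
## is homozygous reference and the father homozygous alternate (or the
## mirror), every fetal-specific read is paternal in origin and the plasma
## fraction of such reads is f/2.

#' Estimate the fetal fraction from plasma allele counts
#'
#' Uses sites where the mother is homozygous for one allele and the father
#' homozygous for the other, so the fetus is an obligate heterozygote and
#' the paternal-specific allele appears in plasma at frequency f/2. The
#' default pooled estimator is \code{f = 2 * sum(fetal-specific reads) /
#' sum(depth)} over usable sites; at mirrored sites (mother hom-alt,
#' father hom-ref) the reference-allele reads count as fetal-specific.
#' A per-site median variant (\code{method = "median"}) is provided for
#' robustness comparisons. Sequencing error is deliberately not subtracted
#' here; it is modeled downstream in the dosage HMM emissions. CNV
#' pseudo-sites and zero-depth sites are excluded.
#'
#' @param counts a [CfdnaCounts-class].
#' @param father,mother [ParentalHaplotypes-class] over site lists that
#'   include the count sites.
#' @param minSites minimum usable sites; fewer raises an explicit
#'   "fetal fraction not estimable" error (distinct from an estimate of 0).
#' @param method \code{"pooled"} (default) or \code{"median"}.
#' @return a [CfdnaCounts-class] identical to \code{counts} but with the
#'   fetal-fraction slot set (clamped to [0, 0.5]); the estimate and the
#'   number of sites used are attached as attributes \code{"ff"} and
#'   \code{"nSitesUsed"}.
#' @export
estimateFetalFraction <- function(counts, father, mother, minSites = 10,
                                  method = c("pooled", "median")) {
  method <- match.arg(method)
  stopifnot(is(counts, "CfdnaCounts"))
  ckey <- siteKey(sites(counts))
  fi <- match(ckey, siteKey(sites(father)))
  mi <- match(ckey, siteKey(sites(mother)))
  gF <- (father@hap1 + father@hap2)[fi]
  gM <- (mother@hap1 + mother@hap2)[mi]
  st <- sites(counts)
  usable_alt <- !is.na(gF) & !is.na(gM) & gM == 0L & gF == 2L
  usable_ref <- !is.na(gF) & !is.na(gM) & gM == 2L & gF == 0L
  usable <- (usable_alt | usable_ref) & counts@depth > 0 & st$kind != "CNV"
  n <- sum(usable)
  if (n < minSites) {
    stop("fetal fraction not estimable: ", n, " usable site(s), need ",
         minSites)
  }
  fetal_reads <- ifelse(usable_alt, counts@altDepth,
                        counts@depth - counts@altDepth)[usable]
  depth <- counts@depth[usable]
  ff <- if (method == "pooled") {
    2 * sum(fetal_reads) / sum(depth)
  } else {
    stats::median(2 * fetal_reads / depth)
  }
  ff <- min(max(ff, 0), 0.5)
  fetalFraction(counts) <- ff
  attr(counts, "ff") <- ff
  attr(counts, "nSitesUsed") <- n
  counts
}
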