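#' @import methods
NULL

#' PhasedPanel: a phased population reference panel
#'
#' Holds the phased haplotypes of a carrier-screening cohort over a filtered
#' site list. Rows of \code{haplotypes} are haplotypes (two consecutive rows
#' per sample), columns are sites in site-table order. \code{pathogenicFlags}
#' records, per haplotype, the ids of pathogenic variants it carries.
#'
#' @slot sites site table (see [siteTable()]).
#' @slot haplotypes integer matrix (H x S) of 0/1 alleles.
#' @slot pathogenicFlags list of length H; each element a character vector of
#'   pathogenic variant ids carried by that haplotype.
#' @exportClass PhasedPanel
setClass("PhasedPanel", representation(
  sites = "data.frame",
  haplotypes = "matrix",
  pathogenicFlags = "list"
))

setValidity("PhasedPanel", function(object) {
  msgs <- character()
  tryCatch(validateSites(object@sites), error = function(e) {
    msgs <<- c(msgs, conditionMessage(e))
  })
  H <- nrow(object@haplotypes)
  if (H %% 2 != 0) msgs <- c(msgs, "haplotype count must be even (two per sample)")
  if (ncol(object@haplotypes) != nrow(object@sites)) {
    msgs <- c(msgs, "haplotype matrix columns must match the site table")
  }
  vals <- object@haplotypes
  if (length(vals) > 0 && !all(vals %in% c(0L, 1L))) {
    msgs <- c(msgs, "haplotype alleles must be 0/1")
  }
  if (length(object@pathogenicFlags) != H) {
    msgs <- c(msgs, "pathogenicFlags must have one element per haplotype")
  }
  known <- stats::na.omit(object@sites$id)
  unknown <- setdiff(unlist(object@pathogenicFlags), known)
  if (length(unknown) > 0) {
    msgs <- c(msgs, paste0("pathogenic flag not among site ids: ",
                           paste(unknown, collapse = ", ")))
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Construct a PhasedPanel
#'
#' @param sites site table.
#' @param haplotypes H x S 0/1 matrix, two rows per sample.
#' @param pathogenicFlags list of per-haplotype variant-id vectors; defaults
#'   to flags derived from the alt allele at pathogenic (id-bearing) sites.
#' @return a [PhasedPanel-class] object.
#' @export
PhasedPanel <- function(sites, haplotypes, pathogenicFlags = NULL) {
  storage.mode(haplotypes) <- "integer"
  if (is.null(pathogenicFlags)) {
    flagged <- which(!is.na(sites$id))
    pathogenicFlags <- lapply(seq_len(nrow(haplotypes)), function(h) {
      sites$id[flagged[haplotypes[h, flagged] == 1L]]
    })
  }
  new("PhasedPanel", sites = sites, haplotypes = haplotypes,
      pathogenicFlags = pathogenicFlags)
}

#' ParentalHaplotypes: one parent's two phased haplotypes
#'
#' \code{hap1}/\code{hap2} are 0/1 allele vectors over the site table; an
#' \code{NA} pair at a heterozygous site marks it unphased (family-based
#' phasing leaves triple-heterozygous sites unresolved). \code{pathogenicLabel}
#' names, per haplotype, the pathogenic variant ids it carries, so the dosage
#' decoder can label hypotheses pathogenic/normal.
#'
#' @slot sites site table.
#' @slot hap1 integer vector of 0/1/NA alleles.
#' @slot hap2 integer vector of 0/1/NA alleles.
#' @slot pathogenicLabel list with elements \code{hap1}, \code{hap2}, each a
#'   character vector of variant ids.
#' @slot source character: \code{"PBH"}, \code{"FBH"}, or \code{"truth"}.
#' @exportClass ParentalHaplotypes
setClass("ParentalHaplotypes", representation(
  sites = "data.frame",
  hap1 = "integer",
  hap2 = "integer",
  pathogenicLabel = "list",
  source = "character"
))

setValidity("ParentalHaplotypes", function(object) {
  msgs <- character()
  tryCatch(validateSites(object@sites), error = function(e) {
    msgs <<- c(msgs, conditionMessage(e))
  })
  S <- nrow(object@sites)
  if (length(object@hap1) != S || length(object@hap2) != S) {
    msgs <- c(msgs, "hap1/hap2 length must match the site table")
  }
  ok <- function(v) all(is.na(v) | v %in% c(0L, 1L))
  if (!ok(object@hap1) || !ok(object@hap2)) {
    msgs <- c(msgs, "haplotype alleles must be 0/1 or NA")
  }
  if (any(is.na(object@hap1) != is.na(object@hap2))) {
    msgs <- c(msgs, "hap1 and hap2 must be NA at the same (unphased) sites")
  }
  if (!all(c("hap1", "hap2") %in% names(object@pathogenicLabel))) {
    msgs <- c(msgs, "pathogenicLabel must have elements hap1 and hap2")
  }
  if (!object@source %in% c("PBH", "FBH", "truth")) {
    msgs <- c(msgs, "source must be one of PBH, FBH, truth")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Construct a ParentalHaplotypes object
#'
#' @param sites site table.
#' @param hap1,hap2 0/1 allele vectors (NA = unphased at that site).
#' @param source phasing provenance: \code{"PBH"}, \code{"FBH"}, or
#'   \code{"truth"}.
#' @param pathogenicLabel list(hap1 =, hap2 =) of carried variant ids;
#'   derived from alt alleles at id-bearing sites when \code{NULL}.
#' @return a [ParentalHaplotypes-class] object.
#' @export
ParentalHaplotypes <- function(sites, hap1, hap2, source = "truth",
                               pathogenicLabel = NULL) {
  hap1 <- as.integer(hap1)
  hap2 <- as.integer(hap2)
  if (is.null(pathogenicLabel)) {
    flagged <- which(!is.na(sites$id))
    pathogenicLabel <- list(
      hap1 = sites$id[flagged[which(hap1[flagged] == 1L)]],
      hap2 = sites$id[flagged[which(hap2[flagged] == 1L)]]
    )
  }
  new("ParentalHaplotypes", sites = sites, hap1 = hap1, hap2 = hap2,
      pathogenicLabel = pathogenicLabel, source = source)
}

#' CfdnaCounts: plasma allele counts at candidate sites
#'
#' Per-site total and alt-allele read depths observed in maternal plasma
#' cell-free DNA, plus the estimated fetal fraction once computed.
#'
#' @slot sites site table.
#' @slot depth integer vector of total read depths.
#' @slot altDepth integer vector of alt-allele read depths.
#' @slot ff numeric fetal fraction in [0, 0.5]; NA until estimated.
#' @exportClass CfdnaCounts
setClass("CfdnaCounts", representation(
  sites = "data.frame",
  depth = "integer",
  altDepth = "integer",
  ff = "numeric"
))

setValidity("CfdnaCounts", function(object) {
  msgs <- character()
  tryCatch(validateSites(object@sites), error = function(e) {
    msgs <<- c(msgs, conditionMessage(e))
  })
  S <- nrow(object@sites)
  if (length(object@depth) != S || length(object@altDepth) != S) {
    msgs <- c(msgs, "depth/altDepth length must match the site table")
  }
  if (any(object@depth < 0, na.rm = TRUE) ||
      any(object@altDepth < 0, na.rm = TRUE) ||
      any(object@altDepth > object@depth, na.rm = TRUE)) {
    msgs <- c(msgs, "require 0 <= altDepth <= depth")
  }
  if (length(object@ff) != 1 ||
      (!is.na(object@ff) && (object@ff < 0 || object@ff > 0.5))) {
    msgs <- c(msgs, "ff must be a single value in [0, 0.5] (or NA)")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Construct a CfdnaCounts object
#'
#' @param sites site table.
#' @param depth,altDepth integer read counts per site.
#' @param ff fetal fraction (NA until estimated).
#' @return a [CfdnaCounts-class] object.
#' @export
CfdnaCounts <- function(sites, depth, altDepth, ff = NA_real_) {
  S <- nrow(sites)
  new("CfdnaCounts", sites = sites,
      depth = rep(as.integer(depth), length.out = S),
      altDepth = rep(as.integer(altDepth), length.out = S),
      ff = as.numeric(ff))
}
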