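#' Accessors for hapdose containers
#'
#' @param x a [PhasedPanel-class], [ParentalHaplotypes-class] or
#'   [CfdnaCounts-class] object.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("pathogenicFlags", function(x) standardGeneric("pathogenicFlags"))

#' @rdname accessors
#' @export
setGeneric("genotypeDosage", function(x) standardGeneric("genotypeDosage"))

#' @rdname accessors
#' @export
setGeneric("fetalFraction", function(x) standardGeneric("fetalFraction"))

#' @rdname accessors
#' @export
setGeneric("fetalFraction<-", function(x, value) standardGeneric("fetalFraction<-"))

#' @rdname accessors
setMethod("sites", "PhasedPanel", function(x) x@sites)
#' @rdname accessors
setMethod("sites", "ParentalHaplotypes", function(x) x@sites)
#' @rdname accessors
setMethod("sites", "CfdnaCounts", function(x) x@sites)

#' @rdname accessors
setMethod("haplotypes", "PhasedPanel", function(x) x@haplotypes)
#' @rdname accessors
setMethod("haplotypes", "ParentalHaplotypes", function(x) {
  m <- rbind(hap1 = x@hap1, hap2 = x@hap2)
  colnames(m) <- siteKey(x@sites)
  m
})

#' @rdname accessors
setMethod("nHaplotypes", "PhasedPanel", function(x) nrow(x@haplotypes))
#' @rdname accessors
setMethod("nSamples", "PhasedPanel", function(x) nrow(x@haplotypes) %/% 2L)

#' @rdname accessors
setMethod("pathogenicFlags", "PhasedPanel", function(x) x@pathogenicFlags)
#' @rdname accessors
setMethod("pathogenicFlags", "ParentalHaplotypes", function(x) x@pathogenicLabel)

#' @rdname accessors
setMethod("genotypeDosage", "ParentalHaplotypes", function(x) x@hap1 + x@hap2)

#' @rdname accessors
setMethod("fetalFraction", "CfdnaCounts", function(x) x@ff)
#' @rdname accessors
setReplaceMethod("fetalFraction", "CfdnaCounts", function(x, value) {
  x@ff <- as.numeric(value)
  validObject(x)
  x
})

setMethod("show", "PhasedPanel", function(object) {
  cat(sprintf("PhasedPanel: %d haplotypes (%d samples) x %d sites\n",
              nrow(object@haplotypes), nrow(object@haplotypes) %/% 2L,
              nrow(object@sites)))
  n_flag <- sum(lengths(object@pathogenicFlags) > 0)
  cat(sprintf("  pathogenic-variant-carrying haplotypes: %d\n", n_flag))
  if (nrow(object@sites) > 0) {
    cat(sprintf("  span: %s:%d-%d\n", object@sites$chrom[1],
                min(object@sites$pos), max(object@sites$pos)))
  }
  invisible(NULL)
})

setMethod("show", "ParentalHaplotypes", function(object) {
  gt <- object@hap1 + object@hap2
  cat(sprintf("ParentalHaplotypes (%s): %d sites, %d het, %d unphased\n",
              object@source, nrow(object@sites),
              sum(gt == 1L, na.rm = TRUE), sum(is.na(object@hap1))))
  lab <- function(v) if (length(v) == 0) "normal" else paste(v, collapse = ",")
  cat(sprintf("  hap1: %s\n  hap2: %s\n",
              lab(object@pathogenicLabel$hap1),
              lab(object@pathogenicLabel$hap2)))
  invisible(NULL)
})

setMethod("show", "CfdnaCounts", function(object) {
  cat(sprintf("CfdnaCounts: %d sites, mean depth %.1f, fetal fraction %s\n",
              nrow(object@sites), mean(object@depth),
              if (is.na(object@ff)) "not estimated"
              else sprintf("%.3f", object@ff)))
  invisible(NULL)
})
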