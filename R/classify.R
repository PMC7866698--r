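## Fetal status classification, the invasive-referral rule, and cohort
## aggregation: the clinical layer that turns per-parent allele calls into
## the summary a reporting lab would print.

#' Canonical allele string of an allele call
#'
#' \code{"N"} for a normal call, the variant id for a pathogenic call,
#' \code{"NC"} for a no-call.
#'
#' @param call an \code{"AlleleCall"} or an already-canonical string.
#' @return character scalar.
#' @export
alleleString <- function(call) {
  if (is.character(call)) return(call)
  switch(call$call, normal = "N", no_call = "NC", pathogenic = call$variantId)
}

#' Classify a fetus from its two allele calls
#'
#' Both pathogenic: affected; exactly one pathogenic (other normal):
#' carrier; both normal: normal; exactly one no-call: partial; two
#' no-calls: failed.
#'
#' @param mat,pat maternal and paternal calls (\code{"AlleleCall"} objects
#'   or canonical allele strings).
#' @return status string: \code{"normal"}, \code{"carrier"},
#'   \code{"affected"}, \code{"partial"}, or \code{"failed"}.
#' @export
classifyFetus <- function(mat, pat) {
  m <- alleleString(mat)
  p <- alleleString(pat)
  n_nc <- (m == "NC") + (p == "NC")
  if (n_nc == 2) return("failed")
  if (n_nc == 1) return("partial")
  n_path <- (m != "N") + (p != "N")
  c("normal", "carrier", "affected")[n_path + 1]
}

#' Should invasive prenatal diagnosis be recommended?
#'
#' TRUE for an affected fetus, for a partial result whose called allele is
#' pathogenic, and for a failed (double no-call) result — conservatively,
#' since nothing was ruled out. Normal and carrier fetuses with both
#' alleles called need no confirmation.
#'
#' @param mat,pat maternal and paternal calls (objects or strings).
#' @return logical scalar.
#' @export
recommendInvasive <- function(mat, pat) {
  m <- alleleString(mat)
  p <- alleleString(pat)
  status <- classifyFetus(m, p)
  if (status == "affected") return(TRUE)
  if (status == "failed") return(TRUE)
  if (status == "partial") {
    called <- setdiff(c(m, p), "NC")
    return(any(called != "N"))
  }
  FALSE
}

#' Read a cohort results table
#'
#' Tab-separated per-family results: columns \code{family, gene, ff,
#' nipt_mat, nipt_pat} and optionally \code{invasive_mat, invasive_pat}
#' (invasive-diagnosis allele strings for validation), \code{cs_mat,
#' cs_pat} (confidence scores in percent) and informative-SNP counts. The
#' package ships such a table for a 59-family thalassemia cohort under
#' \code{system.file("extdata", "thalassemia_cohort.tsv", package =
#' "hapdose")}.
#'
#' @param path TSV file.
#' @return \code{data.frame}.
#' @export
readCohortTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "gene", "ff", "nipt_mat", "nipt_pat")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df
}

#' Summarize a cohort of fetal results
#'
#' Direct tabulation of per-family NIPT outcomes: allele-level call rate,
#' classification counts among fully called fetuses, invasive-referral
#' reduction, mean fetal fraction, and — where invasive validation alleles
#' are present — per-allele concordance with a Clopper-Pearson 95\%
#' confidence interval. No-call alleles never enter the concordance
#' denominator. Permutation-invariant in the family list.
#'
#' @param results cohort \code{data.frame} (see [readCohortTable()]).
#' @return a \code{"CohortSummary"} list of counts and rates (rates as
#'   proportions; \code{mean_ff} on the scale of the \code{ff} column).
#' @export
summarizeCohort <- function(results) {
  stopifnot(nrow(results) > 0)
  m <- results$nipt_mat
  p <- results$nipt_pat
  status <- mapply(classifyFetus, m, p)
  invasive <- mapply(recommendInvasive, m, p)
  n <- nrow(results)
  n_called <- sum(m != "NC") + sum(p != "NC")
  both <- status %in% c("normal", "carrier", "affected")
  partial <- status == "partial"
  partial_path <- partial & ifelse(m == "NC", p != "N" & p != "NC",
                                   m != "N" & m != "NC")
  out <- list(
    n_families = n,
    n_alleles_total = 2L * n,
    n_alleles_called = n_called,
    call_rate = n_called / (2 * n),
    n_no_call = 2L * n - n_called,
    n_both = sum(both),
    n_normal = sum(status == "normal"),
    n_carrier = sum(status == "carrier"),
    n_affected = sum(status == "affected"),
    n_partial = sum(partial),
    n_partial_pathogenic = sum(partial_path),
    n_failed = sum(status == "failed"),
    n_invasive_recommended = sum(invasive),
    invasive_reduction = 1 - sum(invasive) / n,
    mean_ff = mean(results$ff)
  )
  if (all(c("invasive_mat", "invasive_pat") %in% names(results)) &&
      n_called > 0) {
    conc <- c((m == results$invasive_mat)[m != "NC"],
              (p == results$invasive_pat)[p != "NC"])
    ci <- stats::binom.test(sum(conc), length(conc))$conf.int
    out$n_concordant <- sum(conc)
    out$n_discordant <- sum(!conc)
    out$concordance_rate <- mean(conc)
    out$concordance_ci <- as.numeric(ci)
  } else {
    out$n_concordant <- NA_integer_
    out$n_discordant <- NA_integer_
    out$concordance_rate <- NA_real_
    out$concordance_ci <- c(NA_real_, NA_real_)
  }
  structure(out, class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("Cohort of %d families (%d alleles)\n",
              x$n_families, x$n_alleles_total))
  cat(sprintf("  alleles called: %d/%d (%.1f%%)\n", x$n_alleles_called,
              x$n_alleles_total, 100 * x$call_rate))
  cat(sprintf("  both-allele fetuses: %d (normal %d, carrier %d, affected %d)\n",
              x$n_both, x$n_normal, x$n_carrier, x$n_affected))
  cat(sprintf("  one-allele fetuses: %d (%d with the called allele pathogenic)\n",
              x$n_partial, x$n_partial_pathogenic))
  if (!is.na(x$concordance_rate)) {
    cat(sprintf("  concordance with invasive diagnosis: %d/%d (%.1f%%; 95%% CI %.1f-%.1f%%)\n",
                x$n_concordant, x$n_concordant + x$n_discordant,
                100 * x$concordance_rate, 100 * x$concordance_ci[1],
                100 * x$concordance_ci[2]))
  }
  cat(sprintf("  invasive diagnosis recommended: %d (%.1f%% reduction)\n",
              x$n_invasive_recommended, 100 * x$invasive_reduction))
  # one decimal for display; the raw value stays in the object
  cat(sprintf("  mean fetal fraction: %.1f\n", x$mean_ff))
  invisible(x)
}

#' Collect inferFetus() output into a cohort results row
#'
#' @param family family id.
#' @param gene target-gene name.
#' @param result one element of the [inferFetus()] return value.
#' @param invasive optional character vector \code{c(mat, pat)} of invasive
#'   validation alleles.
#' @return one-row \code{data.frame} in the cohort-table layout (fetal
#'   fraction in percent, confidence scores as rounded percent).
#' @export
fetalResultRow <- function(family, gene, result, invasive = NULL) {
  df <- data.frame(
    family = family, gene = gene, ff = round(100 * result$ff, 1),
    snps_mp = result$maternal$nSnpsHapP, snps_mn = result$maternal$nSnpsHapN,
    snps_pp = result$paternal$nSnpsHapP, snps_pn = result$paternal$nSnpsHapN,
    cs_mat = round(100 * result$maternal$cs),
    cs_pat = round(100 * result$paternal$cs),
    nipt_mat = alleleString(result$maternal),
    nipt_pat = alleleString(result$paternal),
    stringsAsFactors = FALSE
  )
  if (!is.null(invasive)) {
    df$invasive_mat <- invasive[1]
    df$invasive_pat <- invasive[2]
  }
  df
}
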