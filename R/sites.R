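#' Build a site table
#'
#' A site table is the package's common currency for biallelic loci: SNPs,
#' small InDels, and copy-number variants (CNVs) encoded as pseudo-SNPs.
#' Coordinates are 1-based and inclusive throughout (VCF convention). For a
#' CNV, \code{pos} is the start of the event and \code{cnv_end} its 1-based
#' inclusive end; plain consumers see an ordinary biallelic record.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt allele strings.
#' @param kind one of \code{"SNP"}, \code{"INDEL"}, \code{"CNV"} (recycled).
#' @param cnv_end 1-based inclusive end position, required where
#'   \code{kind == "CNV"}, \code{NA} otherwise.
#' @param id optional variant identifiers (e.g. \code{"c.52A>T"}, \code{"--SEA"}).
#' @return a \code{data.frame} with columns \code{chrom, pos, id, ref, alt,
#'   kind, cnv_end}, sorted by \code{(chrom, pos)}.
#' @examples
#' siteTable("11", c(5248232, 5247153), ref = c("A", "CTTTT"),
#'           alt = c("T", "C"), kind = c("SNP", "INDEL"))
#' @export
siteTable <- function(chrom, pos, ref, alt, kind = "SNP", cnv_end = NA_integer_,
                      id = NA_character_) {
  if (length(pos) == 0) {
    df <- data.frame(chrom = character(0), pos = integer(0),
                     id = character(0), ref = character(0),
                     alt = character(0), kind = character(0),
                     cnv_end = integer(0), stringsAsFactors = FALSE)
    return(df)
  }
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    id = as.character(id),
    ref = as.character(ref),
    alt = as.character(alt),
    kind = as.character(kind),
    cnv_end = as.integer(cnv_end),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  validateSites(df)
  df
}

SITE_COLS <- c("chrom", "pos", "id", "ref", "alt", "kind", "cnv_end")

#' Validate a site table
#'
#' Checks the site-table invariants: positive 1-based positions, known
#' variant kinds, \code{cnv_end >= pos} for CNVs, and uniqueness of
#' \code{(chrom, pos, ref, alt)}.
#'
#' @param sites a site table as returned by [siteTable()].
#' @return the table, invisibly; errors describe the offending row.
#' @export
validateSites <- function(sites) {
  stopifnot(is.data.frame(sites))
  missing_cols <- setdiff(SITE_COLS, names(sites))
  if (length(missing_cols) > 0) {
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(sites) == 0) return(invisible(sites))
  if (any(is.na(sites$pos)) || any(sites$pos < 1)) {
    stop("site positions must be 1-based positive integers")
  }
  bad_kind <- !sites$kind %in% c("SNP", "INDEL", "CNV")
  if (any(bad_kind)) {
    stop("unknown site kind at row ", which(bad_kind)[1], ": ",
         sites$kind[which(bad_kind)[1]])
  }
  cnv <- sites$kind == "CNV"
  if (any(cnv & (is.na(sites$cnv_end) | sites$cnv_end < sites$pos))) {
    stop("CNV sites require cnv_end >= pos")
  }
  key <- siteKey(sites)
  if (anyDuplicated(key)) {
    stop("duplicate site record: ", key[duplicated(key)][1])
  }
  invisible(sites)
}

siteKey <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

sameSites <- function(a, b) {
  nrow(a) == nrow(b) && all(siteKey(a) == siteKey(b))
}

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
sitesToGRanges <- function(sites) {
  end <- ifelse(sites$kind == "CNV", sites$cnv_end, sites$pos)
  GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, end))
}

#' Define a target gene
#'
#' A target gene couples a genomic interval (1-based, closed) with the set
#' of pathogenic sites screened at that locus; the inheritance caller reports
#' one maternal and one paternal allele per target.
#'
#' @param name gene label, e.g. \code{"HBB"} or \code{"HBA"}.
#' @param chrom chromosome of the target interval.
#' @param start,end 1-based closed interval bounds.
#' @param pathogenicSites site table of the pathogenic variants at this locus
#'   (ids must be non-missing).
#' @return an object of class \code{"TargetGene"} (a named list).
#' @export
targetGene <- function(name, chrom, start, end, pathogenicSites) {
  validateSites(pathogenicSites)
  stopifnot(start >= 1, end >= start)
  if (any(is.na(pathogenicSites$id))) {
    stop("pathogenic sites must carry a variant id")
  }
  ps_end <- ifelse(pathogenicSites$kind == "CNV",
                   pathogenicSites$cnv_end, pathogenicSites$pos)
  overlaps <- pathogenicSites$chrom == chrom &
    pathogenicSites$pos <= end & ps_end >= start
  if (!all(overlaps)) {
    stop("pathogenic site(s) outside the target interval: ",
         paste(pathogenicSites$id[!overlaps], collapse = ", "))
  }
  structure(
    list(name = name, chrom = as.character(chrom),
         start = as.integer(start), end = as.integer(end),
         pathogenicSites = pathogenicSites),
    class = "TargetGene"
  )
}

#' @export
print.TargetGene <- function(x, ...) {
  cat(sprintf("TargetGene %s  %s:%d-%d  (%d pathogenic site%s)\n",
              x$name, x$chrom, x$start, x$end, nrow(x$pathogenicSites),
              if (nrow(x$pathogenicSites) == 1) "" else "s"))
  invisible(x)
}

targetMidpoint <- function(target) {
  (target$start + target$end) / 2
}
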