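## I/O for the VCF-like dialects the pipeline consumes and emits.
## Coordinates are 1-based inclusive everywhere; BED input (0-based,
## half-open) is converted on read by rtracklayer. CNVs travel as
## pseudo-SNP records flagged in INFO with KIND=CNV;CNVEND=<end>, so a
## plain VCF consumer sees an ordinary biallelic record.

vcfFixToSites <- function(fix) {
  info <- fix[, "INFO"]
  kind <- ifelse(grepl("KIND=CNV", info), "CNV",
                 ifelse(nchar(fix[, "REF"]) != nchar(fix[, "ALT"]),
                        "INDEL", "SNP"))
  cnv_end <- suppressWarnings(
    as.integer(sub(".*CNVEND=([0-9]+).*", "\\1", info))
  )
  cnv_end[kind != "CNV"] <- NA_integer_
  id <- fix[, "ID"]
  id[id == "." | id == ""] <- NA_character_
  data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = id, ref = fix[, "REF"], alt = fix[, "ALT"],
    kind = kind, cnv_end = cnv_end, stringsAsFactors = FALSE
  )
}

parseGtField <- function(gt, where) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
    return(list(a = NA_integer_, b = NA_integer_, phased = FALSE))
  }
  m <- regmatches(gt, regexec("^([01])([/|])([01])", gt))[[1]]
  if (length(m) == 0) stop("malformed GT '", gt, "' at ", where)
  list(a = as.integer(m[2]), b = as.integer(m[4]), phased = m[3] == "|")
}

#' Read a genotype table from VCF
#'
#' Reads per-sample genotypes with read depths from a VCF 4.2 file carrying
#' GT and (optionally) AD/DP FORMAT fields. CNV pseudo-SNP records (INFO
#' \code{KIND=CNV;CNVEND=<end>}) are decoded; genotypes "0/1" and "1/1" at
#' such records mean heterozygous and homozygous CNV. Multi-allelic records
#' are rejected (the method is defined on biallelic sites), as are duplicate
#' \code{(chrom, pos, ref, alt)} records. Sites with missing AD get
#' \code{depth = alt_depth = 0} and are excluded downstream from ratio-based
#' computations rather than imputed.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sampleIds samples to extract; default all samples in the file.
#' @return named list: one \code{data.frame} per sample with the site columns
#'   plus \code{allele_a, allele_b, phased, depth, alt_depth}, sorted by
#'   \code{(chrom, pos)}.
#' @export
readGenotypeTable <- function(path, sampleIds = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    bad <- which(grepl(",", fix[, "ALT"], fixed = TRUE))[1]
    stop("multi-allelic record at ", fix[bad, "CHROM"], ":", fix[bad, "POS"],
         " rejected; split or drop it upstream")
  }
  st <- vcfFixToSites(fix)
  dup <- duplicated(siteKey(st))
  if (any(dup)) {
    stop("duplicate site record at line for ", siteKey(st)[which(dup)[1]])
  }
  gt_all <- vcfR::extract.gt(vcf, element = "GT")
  ad_all <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                     error = function(e) NULL)
  dp_all <- tryCatch(vcfR::extract.gt(vcf, element = "DP"),
                     error = function(e) NULL)
  found <- colnames(gt_all)
  if (is.null(sampleIds)) sampleIds <- found
  missing_s <- setdiff(sampleIds, found)
  if (length(missing_s) > 0) {
    stop("sample(s) not in VCF: ", paste(missing_s, collapse = ", "))
  }
  ord <- order(st$chrom, st$pos, st$ref, st$alt)
  out <- lapply(sampleIds, function(s) {
    n <- nrow(st)
    allele_a <- allele_b <- rep(NA_integer_, n)
    phased <- logical(n)
    depth <- alt_depth <- integer(n)
    for (i in seq_len(n)) {
      where <- paste0(st$chrom[i], ":", st$pos[i], " sample ", s)
      g <- parseGtField(gt_all[i, s], where)
      allele_a[i] <- g$a; allele_b[i] <- g$b; phased[i] <- g$phased
      ad <- if (is.null(ad_all)) NA_character_ else ad_all[i, s]
      if (!is.na(ad) && ad != ".") {
        counts <- suppressWarnings(as.integer(strsplit(ad, ",")[[1]]))
        if (length(counts) != 2 || anyNA(counts)) {
          stop("malformed AD '", ad, "' at ", where)
        }
        alt_depth[i] <- counts[2]
        depth[i] <- sum(counts)
        dp <- if (is.null(dp_all)) NA_character_ else dp_all[i, s]
        if (!is.na(dp) && dp != "." && as.integer(dp) != depth[i]) {
          stop("AD (", ad, ") inconsistent with DP (", dp, ") at ", where)
        }
      }
    }
    df <- cbind(st, data.frame(allele_a, allele_b, phased, depth, alt_depth))
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(out) <- sampleIds
  out
}

#' Write phased haplotypes to VCF
#'
#' Writes one phased VCF 4.2 record per site with the "|" GT separator;
#' unphased sites are written as "./.". CNV pseudo-sites carry
#' \code{KIND=CNV;CNVEND} in INFO so a round-trip through
#' [readPhasedVcf()] restores the site table exactly.
#'
#' @param haplotypes named list of [ParentalHaplotypes-class], all over one
#'   site list.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePhasedVcf <- function(haplotypes, path) {
  stopifnot(is.list(haplotypes), length(haplotypes) > 0,
            !is.null(names(haplotypes)))
  ref_sites <- sites(haplotypes[[1]])
  for (s in names(haplotypes)) {
    if (!sameSites(sites(haplotypes[[s]]), ref_sites)) {
      stop("sample '", s, "' has a different site list")
    }
  }
  info <- ifelse(ref_sites$kind == "CNV",
                 paste0("KIND=CNV;CNVEND=", ref_sites$cnv_end), ".")
  id <- ifelse(is.na(ref_sites$id), ".", ref_sites$id)
  gt_cols <- vapply(haplotypes, function(h) {
    ifelse(is.na(h@hap1), "./.", paste0(h@hap1, "|", h@hap2))
  }, character(nrow(ref_sites)))
  gt_cols <- matrix(gt_cols, nrow = nrow(ref_sites))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Site kind (CNV pseudo-SNP flag)\">",
    "##INFO=<ID=CNVEND,Number=1,Type=Integer,Description=\"1-based inclusive CNV end\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(haplotypes)), collapse = "\t")
  )
  body <- apply(
    cbind(ref_sites$chrom, ref_sites$pos, id, ref_sites$ref, ref_sites$alt,
          ".", "PASS", info, "GT", gt_cols),
    1, paste, collapse = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased haplotypes from VCF
#'
#' Inverse of [writePhasedVcf()]: phased GT ("|") becomes hap1/hap2;
#' "./." marks unphased sites (both haplotype alleles NA).
#'
#' @param path phased VCF.
#' @param source provenance label stored on the returned objects
#'   (\code{"PBH"}, \code{"FBH"}, or \code{"truth"}).
#' @return named list of [ParentalHaplotypes-class].
#' @export
readPhasedVcf <- function(path, source = "PBH") {
  gts <- readGenotypeTable(path)
  lapply(gts, function(df) {
    unphased <- !df$phased & !is.na(df$allele_a) & df$allele_a != df$allele_b
    hap1 <- ifelse(unphased, NA_integer_, df$allele_a)
    hap2 <- ifelse(unphased, NA_integer_, df$allele_b)
    ParentalHaplotypes(df[, SITE_COLS], hap1, hap2, source = source)
  })
}

#' Read target intervals from BED
#'
#' BED is 0-based half-open; rtracklayer converts to the 1-based closed
#' convention used throughout this package.
#'
#' @param path BED file; the name column labels the target gene.
#' @return a \code{GRanges} of target intervals.
#' @export
readBedTargets <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read a pathogenic-variant configuration
#'
#' YAML (or JSON) file listing pathogenic variants, each with fields
#' \code{id, chrom, pos, ref, alt, kind, gene} and \code{cnv_end} for CNVs.
#'
#' @param path YAML/JSON file.
#' @return site table with an extra \code{gene} column.
#' @export
readVariantConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  vars <- cfg$variants %||% cfg
  df <- do.call(rbind, lapply(vars, function(v) {
    data.frame(
      chrom = as.character(v$chrom), pos = as.integer(v$pos),
      id = as.character(v$id), ref = as.character(v$ref),
      alt = as.character(v$alt), kind = v$kind %||% "SNP",
      cnv_end = as.integer(v$cnv_end %||% NA), gene = as.character(v$gene),
      stringsAsFactors = FALSE
    )
  }))
  validateSites(df[, SITE_COLS])
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble target genes from BED intervals and a variant list
#'
#' @param bed \code{GRanges} from [readBedTargets()] with a \code{name}
#'   column naming each gene.
#' @param variants variant table from [readVariantConfig()].
#' @return named list of \code{TargetGene}.
#' @export
makeTargets <- function(bed, variants) {
  nm <- bed$name
  out <- lapply(seq_along(bed), function(i) {
    vs <- variants[variants$gene == nm[i], SITE_COLS, drop = FALSE]
    targetGene(nm[i], as.character(GenomicRanges::seqnames(bed)[i]),
               GenomicRanges::start(bed)[i], GenomicRanges::end(bed)[i], vs)
  })
  names(out) <- nm
  out
}

#' Read cfDNA allele counts from TSV
#'
#' Tab-separated dialect: columns \code{chrom, pos, ref, alt, depth,
#' alt_depth}, optionally \code{id, kind, cnv_end}.
#'
#' @param path TSV file.
#' @return a [CfdnaCounts-class] object (fetal fraction not yet estimated).
#' @export
readCfdnaTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  if (is.null(df$id)) df$id <- NA_character_
  if (is.null(df$kind)) df$kind <- "SNP"
  if (is.null(df$cnv_end)) df$cnv_end <- NA_integer_
  df$id <- as.character(df$id)
  df$kind <- as.character(df$kind)
  df$cnv_end <- as.integer(df$cnv_end)
  df$pos <- as.integer(df$pos)
  st <- df[, SITE_COLS]
  ord <- order(st$chrom, st$pos, st$ref, st$alt)
  validateSites(st[ord, , drop = FALSE])
  CfdnaCounts(`rownames<-`(st[ord, , drop = FALSE], NULL),
              df$depth[ord], df$alt_depth[ord])
}

#' Write cfDNA allele counts to TSV
#'
#' @param counts a [CfdnaCounts-class] object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCfdnaTsv <- function(counts, path) {
  df <- cbind(sites(counts),
              data.frame(depth = counts@depth, alt_depth = counts@altDepth))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
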