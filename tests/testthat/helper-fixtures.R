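# Small in-code fixtures shared across the suite.

# n biallelic SNP sites on one chromosome, evenly spaced
toySites <- function(n, chrom = "11", start = 5200000, by = 2000,
                     ids = NULL) {
  st <- siteTable(chrom, start + by * (seq_len(n) - 1),
                  ref = rep(c("A", "C", "G", "T"), length.out = n),
                  alt = rep(c("G", "T", "A", "C"), length.out = n))
  if (!is.null(ids)) st$id[seq_along(ids)] <- ids
  st
}

# genotype data.frame from explicit allele pairs
toyGenotypes <- function(st, a, b, depth = 100L, alt_depth = NULL,
                         phased = FALSE) {
  if (is.null(alt_depth)) alt_depth <- as.integer(depth * (a + b) / 2)
  cbind(st, data.frame(allele_a = as.integer(a), allele_b = as.integer(b),
                       phased = phased, depth = as.integer(depth),
                       alt_depth = as.integer(alt_depth)))
}

# a small deterministic panel built from two founder haplotypes
toyPanel <- function(nSamples = 3, nSites = 6, pathogenicId = NULL) {
  st <- toySites(nSites, ids = pathogenicId)
  f1 <- rep(0L, nSites)
  f2 <- rep(1L, nSites)
  haps <- do.call(rbind, rep(list(f1, f2), nSamples))
  PhasedPanel(st, haps)
}

# target gene centred on the toy site grid
toyTarget <- function(st, ids = stats::na.omit(st$id)) {
  ps <- st[!is.na(st$id) & st$id %in% ids, , drop = FALSE]
  targetGene("HBB", st$chrom[1], min(st$pos), max(st$pos), ps)
}

# informative-site frame built directly (bypassing selection) for HMM tests
toyInformative <- function(st, class, allele_p = 1L, allele_n = 0L,
                           other_allele = 0L) {
  n <- nrow(st)
  cbind(st, data.frame(class = rep(class, length.out = n),
                       allele_p = rep(as.integer(allele_p), length.out = n),
                       allele_n = rep(as.integer(allele_n), length.out = n),
                       other_allele = rep(as.integer(other_allele),
                                          length.out = n)))
}

toyCounts <- function(st, depth, alt) {
  CfdnaCounts(st, as.integer(depth), as.integer(alt))
}

cohortFixturePath <- function() {
  system.file("extdata", "thalassemia_cohort.tsv", package = "hapdose")
}
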