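bases <- c("A", "C", "G", "T")

# random but valid site table, sorted by (chrom, pos)
random_sites <- function(n, seed = 1L, chroms = c("chr1", "chr2"),
                         max_pos = 2e6, max_count = 60L) {
  set.seed(seed)
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- sample.int(max_pos, n, replace = TRUE)
  hi <- sample(bases, n, replace = TRUE)
  lo <- vapply(hi, function(b) sample(setdiff(bases, b), 1L), character(1L))
  sites <- data.frame(chrom = chrom, pos = pos, hi_allele = hi, lo_allele = lo,
                      stringsAsFactors = FALSE)
  for (col in c(paste0("T_", bases), paste0("S_", bases))) {
    sites[[col]] <- sample.int(max_count + 1L, n, replace = TRUE) - 1L
  }
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  sites
}

# single site with explicit per-base counts
one_site <- function(counts_T, counts_S, hi = "G", lo = "A",
                     chrom = "chr1", pos = 100L) {
  s <- data.frame(chrom = chrom, pos = pos, hi_allele = hi, lo_allele = lo,
                  stringsAsFactors = FALSE)
  for (b in bases) {
    s[[paste0("T_", b)]] <- if (b %in% names(counts_T)) counts_T[[b]] else 0L
    s[[paste0("S_", b)]] <- if (b %in% names(counts_S)) counts_S[[b]] else 0L
  }
  s
}

# minimal per-site stats frame for sliding_window tests
stats_frame <- function(chrom, pos, delta,
                        index_T = delta, index_S = 0, ed_k = abs(delta)) {
  data.frame(chrom = chrom, pos = pos, snp_index_T = index_T,
             snp_index_S = index_S, delta = delta, ed_k = ed_k,
             stringsAsFactors = FALSE)
}

# windows frame with a single statistic of interest
windows_frame <- function(chrom, start, end, ed_k) {
  w <- data.frame(chrom = chrom, start = start, end = end,
                  n_sites = 1L, mean_ed_k = ed_k, stringsAsFactors = FALSE)
  w
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal four-sample VCF (two parents, two pools) as text
vcf_fixture <- function(records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "KY131\tDN422\tTpool\tSpool"))
  write_lines_tmp(c(header, records), ext = ".vcf")
}

vcf_rec <- function(chrom, pos, ref, alt, gt_hi, gt_lo, ad_T, ad_S) {
  paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT:AD",
        paste0(gt_hi, ":0,0"), paste0(gt_lo, ":0,0"),
        paste0("0/1:", ad_T), paste0("0/1:", ad_S), sep = "\t")
}

extdata <- function(name) system.file("extdata", name, package = "bsascan")

# expand the published haplotype-composition table into per-line genotypes
synthetic_haplotype_population <- function(shuffle_seed = NULL) {
  comp <- read.delim(extdata("synthetic_haplotypes.tsv"),
                     stringsAsFactors = FALSE)
  rows <- list()
  next_id <- 1L
  for (i in seq_len(nrow(comp))) {
    al <- strsplit(comp$pattern[i], "")[[1L]]
    for (j in seq_len(comp$n_rils[i])) {
      rows[[length(rows) + 1L]] <- c(ril_id = sprintf("RIL%03d", next_id),
                                     setNames(al, paste0("locus", seq_along(al))))
      next_id <- next_id + 1L
    }
  }
  geno <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!is.null(shuffle_seed)) {
    set.seed(shuffle_seed)
    geno <- geno[sample.int(nrow(geno)), , drop = FALSE]
    rownames(geno) <- NULL
  }
  geno
}
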