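#' Validate a table of parent-differentiating pooled SNP sites
#'
#' The internal site representation is a plain data frame with one row per
#' biallelic parent-differentiating SNP, polarized so that `hi_allele` is the
#' allele carried by the tolerant (high-phenotype) parent and `lo_allele` the
#' allele carried by the sensitive parent. Per-pool read counts are stored as
#' eight columns, one per base per pool: `T_A..T_T` for the tolerant pool and
#' `S_A..S_T` for the sensitive pool.
#'
#' @param sites data frame with columns `chrom`, `pos`, `hi_allele`,
#'   `lo_allele`, `T_A`, `T_C`, `T_G`, `T_T`, `S_A`, `S_C`, `S_G`, `S_T`.
#' @return `sites`, invisibly, after checks.
#' @export
validate_sites <- function(sites) {
  missing_cols <- setdiff(SITE_COLS, names(sites))
  if (length(missing_cols) > 0L) {
    stop("site table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(sites) > 0L) {
    if (any(sites$hi_allele == sites$lo_allele)) {
      stop("sites with identical parental alleles are not parent-differentiating")
    }
    if (!all(sites$hi_allele %in% BASES) || !all(sites$lo_allele %in% BASES)) {
      stop("parental alleles must be one of A/C/G/T")
    }
    counts <- as.matrix(sites[, SITE_COUNT_COLS])
    if (any(is.na(counts)) || any(counts < 0)) {
      stop("read counts must be non-negative and non-missing")
    }
    if (any(sites$pos < 1)) stop("positions are 1-based; pos must be >= 1")
  }
  invisible(sites)
}

#' Read pooled SNP sites from the tab-separated site format
#'
#' The site TSV dialect has a header line and the twelve columns
#' `chrom pos hi_allele lo_allele T_A T_C T_G T_T S_A S_C S_G S_T`,
#' tab-separated, UTF-8. Positions are 1-based; counts are reads observed
#' per base in the tolerant (`T_`) and sensitive (`S_`) pools.
#'
#' @param path path to a site TSV file.
#' @return data frame of sites (see [validate_sites()]), rows in file order.
#' @seealso [write_tsv_sites()] for the inverse; the two round-trip exactly.
#' @export
read_tsv_sites <- function(path) {
  sites <- read.delim(path, sep = "\t", header = TRUE,
                      colClasses = c(chrom = "character", pos = "integer",
                                     hi_allele = "character", lo_allele = "character"),
                      stringsAsFactors = FALSE)
  missing_cols <- setdiff(SITE_COLS, names(sites))
  if (length(missing_cols) > 0L) {
    stop("site TSV ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  sites <- sites[, SITE_COLS]
  counts <- as.matrix(sites[, SITE_COUNT_COLS])
  bad <- which(rowSums(is.na(counts) | counts < 0) > 0L)
  if (length(bad) > 0L) {
    # +1 for the header line so the message points at the physical file line
    stop("negative or missing count in ", path, " at line ", bad[1L] + 1L)
  }
  validate_sites(sites)
  sites
}

#' Write pooled SNP sites to the tab-separated site format
#'
#' @param sites site data frame (see [validate_sites()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_sites <- function(sites, path) {
  validate_sites(sites)
  write.table(sites[, SITE_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read pooled SNP sites from a VCF with per-sample allele depths
#'
#' Consumes jointly-called variants for the two parents and the two extreme
#' pools. Only biallelic SNPs at which the two parents are opposite
#' homozygotes are informative for pool-contrast statistics; all other
#' records are dropped and tallied in the attached filter report. Pool
#' allele depths are taken from the per-sample `AD` field and polarized so
#' that `hi_allele` is the allele of the tolerant parent.
#'
#' @param path path to a VCF (4.x) file with GT for the parents and AD for
#'   the pools.
#' @param pool_T_sample_id,pool_S_sample_id sample names of the tolerant and
#'   sensitive pools.
#' @param parent_hi_id,parent_lo_id sample names of the tolerant and
#'   sensitive parents.
#' @param min_depth sites where either pool has fewer reads than this are
#'   retained but their statistics are later treated as missing; recorded
#'   here only in the filter report (default 0, i.e. no tally).
#' @return site data frame with attribute `"filter_report"`: a named integer
#'   vector counting records dropped as `multiallelic`, `not_snp`,
#'   `parent_missing`, `parent_het`, `parent_identical`, or `malformed_ad`,
#'   plus `kept`.
#' @export
read_pooled_vcf <- function(path, pool_T_sample_id, pool_S_sample_id,
                            parent_hi_id, parent_lo_id, min_depth = 0L) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  for (id in c(pool_T_sample_id, pool_S_sample_id, parent_hi_id, parent_lo_id)) {
    if (!id %in% samples) {
      stop("sample id '", id, "' not present in ", path,
           " (samples: ", paste(samples, collapse = ", "), ")")
    }
  }
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7L, dimnames = list(NULL, colnames(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")

  report <- c(multiallelic = 0L, not_snp = 0L, parent_missing = 0L,
              parent_het = 0L, parent_identical = 0L, malformed_ad = 0L,
              kept = 0L)
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alt <- fix[i, "ALT"]
    alleles <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1L]])
    if (length(alleles) != 2L) {
      report["multiallelic"] <- report["multiallelic"] + 1L
      next
    }
    if (!all(alleles %in% BASES)) {
      report["not_snp"] <- report["not_snp"] + 1L
      next
    }
    gt_hi <- .parse_gt(gt[i, parent_hi_id])
    gt_lo <- .parse_gt(gt[i, parent_lo_id])
    if (is.null(gt_hi) || is.null(gt_lo)) {
      report["parent_missing"] <- report["parent_missing"] + 1L
      next
    }
    if (gt_hi[1L] != gt_hi[2L] || gt_lo[1L] != gt_lo[2L]) {
      report["parent_het"] <- report["parent_het"] + 1L
      next
    }
    if (gt_hi[1L] == gt_lo[1L]) {
      report["parent_identical"] <- report["parent_identical"] + 1L
      next
    }
    ad_T <- .parse_ad(ad[i, pool_T_sample_id], 2L)
    ad_S <- .parse_ad(ad[i, pool_S_sample_id], 2L)
    if (is.null(ad_T) || is.null(ad_S)) {
      report["malformed_ad"] <- report["malformed_ad"] + 1L
      warning("malformed AD at ", fix[i, "CHROM"], ":", fix[i, "POS"],
              "; site skipped")
      next
    }
    counts_T <- setNames(rep(0L, 4L), BASES)
    counts_S <- setNames(rep(0L, 4L), BASES)
    counts_T[alleles] <- ad_T
    counts_S[alleles] <- ad_S
    row <- data.frame(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                      hi_allele = alleles[gt_hi[1L] + 1L],
                      lo_allele = alleles[gt_lo[1L] + 1L],
                      stringsAsFactors = FALSE)
    row[paste0("T_", BASES)] <- as.list(counts_T)
    row[paste0("S_", BASES)] <- as.list(counts_S)
    report["kept"] <- report["kept"] + 1L
    rows[[i]] <- row
  }
  sites <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        hi_allele = character(), lo_allele = character())
    sites[SITE_COUNT_COLS] <- lapply(SITE_COUNT_COLS, function(x) integer())
  }
  rownames(sites) <- NULL
  validate_sites(sites)
  attr(sites, "filter_report") <- report
  sites
}

# "0/0" or "1|1" -> c(0L, 0L); NULL when missing/ungenotyped
.parse_gt <- function(x) {
  if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NULL)
  parts <- strsplit(x, "[/|]")[[1L]]
  if (length(parts) != 2L || any(parts == ".")) return(NULL)
  as.integer(parts)
}

.parse_ad <- function(x, n_alleles) {
  if (is.na(x)) return(NULL)
  parts <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1L]]))
  if (length(parts) != n_alleles || any(is.na(parts)) || any(parts < 0)) return(NULL)
  parts
}

#' Read gene models from a GFF3 file
#'
#' Extracts features of type `gene`; mRNA, exon and other feature types are
#' ignored. Coordinates are kept 1-based inclusive as in GFF3.
#'
#' @param path path to a GFF3 file.
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else
    paste0("gene", seq_along(gr))
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read marker physical coordinates from a TSV
#'
#' Expects a header and columns `name chrom start end` with 1-based
#' inclusive physical coordinates (e.g. SSR marker positions on the
#' reference genome).
#'
#' @param path path to the marker TSV.
#' @return data frame with columns `name`, `chrom`, `start`, `end`.
#' @export
read_markers_tsv <- function(path) {
  m <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  colClasses = c(name = "character", chrom = "character"))
  need <- c("name", "chrom", "start", "end")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0L) {
    stop("marker TSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(m$start > m$end)) stop("marker with start > end in ", path)
  m[, need]
}

#' Write called regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' starts are shifted down by one and ends kept.
#'
#' @param regions region data frame from [call_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = sprintf("%s_region_%d",
                                   if (!is.null(regions$statistic_name))
                                     regions$statistic_name else "bsa",
                                   seq_len(nrow(regions))))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write called regions as a publication-style table
#'
#' One row per region with 1-based bounds, size in Mb to two decimals and,
#' when gene models were supplied, the overlapping gene count.
#'
#' @param regions region data frame from [call_regions()], optionally with a
#'   `gene_count` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_table <- function(regions, path) {
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    size_mb = sprintf("%.2f", regions$size_bp / 1e6))
  if (!is.null(regions$gene_count)) out$gene_count <- regions$gene_count
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
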