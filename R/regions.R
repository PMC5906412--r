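#' Genome-wide threshold for the windowed ED^k statistic
#'
#' The default rule takes the mean of the non-missing windowed `ED^k`
#' values plus `multiplier` standard deviations, the usual outlier cut for
#' the heavily right-skewed ED^k background. The sample (n-1) SD is the
#' default; the population (n) SD is available for compatibility with
#' moment-style derivations. An empirical quantile rule is available as an
#' alternative.
#'
#' @param windows window data frame from [sliding_window()].
#' @param method `"mean_plus_sd"` (default) or `"quantile"`.
#' @param multiplier SD multiplier for `"mean_plus_sd"` (default 3).
#' @param q probability for `"quantile"` (default 0.995).
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @param stat window column to threshold (default `"mean_ed_k"`).
#' @return threshold value with attributes recording the method and its
#'   parameters.
#' @export
ed_threshold <- function(windows, method = c("mean_plus_sd", "quantile"),
                         multiplier = 3, q = 0.995,
                         sd_type = c("sample", "population"),
                         stat = "mean_ed_k") {
  method <- match.arg(method)
  sd_type <- match.arg(sd_type)
  x <- windows[[stat]]
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("all windows are missing; cannot set a threshold")
  if (length(x) < 10L) warning("fewer than 10 non-missing windows; threshold is unstable")
  if (method == "mean_plus_sd") {
    s <- sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    if (length(x) == 1L) s <- 0
    thr <- mean(x) + multiplier * s
    attr(thr, "method") <- sprintf("mean_plus_%g_sd_%s", multiplier, sd_type)
  } else {
    thr <- unname(quantile(x, q))
    attr(thr, "method") <- sprintf("quantile_%g", q)
  }
  thr
}

#' Call significant genomic regions from windowed statistics
#'
#' Windows whose statistic passes the threshold are unioned into runs;
#' runs separated by at most `merge_gap_bp` are merged into one region;
#' region bounds are rounded outward to multiples of `boundary_rounding`
#' (default the 10 kb window-step grain, matching how such regions are
#' conventionally tabulated), and sizes are reported as `end - start` on
#' that rounded grid.
#'
#' For the ED^k statistic a window exactly at the threshold counts as
#' significant (`>=`, the default); for delta(SNP-index) against a null
#' upper bound use `strict = TRUE` so only windows strictly above the bound
#' are called.
#'
#' @param windows window data frame from [sliding_window()].
#' @param threshold numeric cut applied to `stat`.
#' @param stat window column to test (default `"mean_ed_k"`; use
#'   `"mean_delta"` for the SNP-index method).
#' @param strict if `TRUE` require `stat > threshold`; default `FALSE`
#'   (`>=`).
#' @param merge_gap_bp merge runs separated by at most this many bp
#'   (default the window step recorded on `windows`, else 1e4).
#' @param boundary_rounding round region bounds outward to multiples of
#'   this (default 1e4); use 1 to disable.
#' @return data frame with columns `chrom`, `start`, `end`, `size_bp`,
#'   `statistic_name`, sorted and non-overlapping within chromosome.
#' @export
call_regions <- function(windows, threshold, stat = "mean_ed_k",
                         strict = FALSE, merge_gap_bp = NULL,
                         boundary_rounding = 1e4) {
  if (is.null(merge_gap_bp)) {
    merge_gap_bp <- attr(windows, "step_bp")
    if (is.null(merge_gap_bp)) merge_gap_bp <- 1e4
  }
  v <- windows[[stat]]
  hit <- !is.na(v) & (if (strict) v > threshold else v >= threshold)
  sig <- windows[hit, c("chrom", "start", "end"), drop = FALSE]
  regions <- merge_regions(sig, merge_gap_bp = merge_gap_bp)
  regions <- round_region_bounds(regions, boundary_rounding)
  regions$size_bp <- regions$end - regions$start
  regions$statistic_name <- rep(stat, nrow(regions))
  regions
}

#' Merge overlapping or nearby intervals
#'
#' Collapses intervals on the same chromosome that overlap or whose gap
#' (`next start - previous end - 1`) is at most `merge_gap_bp`. Merging is
#' idempotent: applying it to its own output returns the same intervals.
#'
#' @param intervals data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param merge_gap_bp maximum gap bridged (default 0: only overlapping or
#'   book-ended intervals merge).
#' @return merged data frame sorted by chromosome and start.
#' @export
merge_regions <- function(intervals, merge_gap_bp = 0) {
  if (nrow(intervals) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(intervals, intervals$chrom), function(ch) {
    ch <- ch[order(ch$start, ch$end), , drop = FALSE]
    start <- ch$start[1L]; end <- ch$end[1L]
    res <- list()
    for (i in seq_len(nrow(ch))[-1L]) {
      if (ch$start[i] - end - 1 <= merge_gap_bp) {
        end <- max(end, ch$end[i])
      } else {
        res[[length(res) + 1L]] <- c(start, end)
        start <- ch$start[i]; end <- ch$end[i]
      }
    }
    res[[length(res) + 1L]] <- c(start, end)
    m <- do.call(rbind, res)
    data.frame(chrom = rep(ch$chrom[1L], nrow(m)), start = m[, 1L],
               end = m[, 2L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

round_region_bounds <- function(regions, grain) {
  if (is.null(grain) || grain <= 1 || nrow(regions) == 0L) return(regions)
  regions$start <- floor(regions$start / grain) * grain
  regions$end <- ceiling(regions$end / grain) * grain
  regions
}

#' Count gene models overlapping each region
#'
#' A gene counts if its span shares at least one bp with the region (both
#' 1-based inclusive).
#'
#' @param regions data frame with `chrom`, `start`, `end`.
#' @param genes gene-model data frame from [read_gff3_genes()] (columns
#'   `chrom`, `start`, `end`).
#' @return integer vector of counts, one per region row.
#' @export
count_genes <- function(regions, genes) {
  if (nrow(regions) == 0L) return(integer())
  if (nrow(genes) == 0L) return(rep(0L, nrow(regions)))
  r <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start, regions$end))
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  GenomicRanges::countOverlaps(r, g)
}

#' Physical interval spanned by two flanking markers
#'
#' Converts a pair of flanking markers (1-based inclusive physical
#' coordinates) into the physical QTL interval. Convention `"outer"` takes
#' the left marker's start through the right marker's end — the full
#' physical span usually quoted for a marker interval. Convention
#' `"left_starts"` takes both markers' start coordinates, the tighter edge
#' used when intersecting with an adjacent scan region.
#'
#' @param left,right marker rows (one-row data frames or lists with
#'   `name`, `chrom`, `start`, `end`), `left` upstream of `right`.
#' @param convention `"outer"` (default) or `"left_starts"`.
#' @return list with `chrom`, `phys_start`, `phys_end`, `span_bp`,
#'   `left_marker`, `right_marker`, `convention`.
#' @export
qtl_physical_interval <- function(left, right,
                                  convention = c("outer", "left_starts")) {
  convention <- match.arg(convention)
  if (left$chrom != right$chrom) {
    stop("flanking markers lie on different chromosomes: ",
         left$chrom, " vs ", right$chrom)
  }
  if (left$start >= right$start) {
    stop("left marker must start upstream of the right marker")
  }
  phys_start <- left$start
  phys_end <- if (convention == "outer") right$end else right$start
  list(chrom = left$chrom, phys_start = phys_start, phys_end = phys_end,
       span_bp = phys_end - phys_start,
       left_marker = left$name, right_marker = right$name,
       convention = convention)
}

#' Intersect called regions with a QTL interval
#'
#' `span_mode = "union_span"` first collapses all regions on the interval's
#' chromosome to their overall span `[min start, max end]` — bridging the
#' gaps between adjacent called regions — and intersects that span with the
#' interval, returning a single region (the convention used when quoting
#' one refined candidate interval). `span_mode = "strict"` intersects each
#' region separately and returns the clipped regions.
#'
#' @param regions region data frame (`chrom`, `start`, `end`).
#' @param interval interval from [qtl_physical_interval()].
#' @param span_mode `"union_span"` (default) or `"strict"`.
#' @return data frame of intersected regions with `size_bp = end - start`;
#'   zero rows when there is no overlap.
#' @export
intersect_with_interval <- function(regions, interval,
                                    span_mode = c("union_span", "strict")) {
  span_mode <- match.arg(span_mode)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      size_bp = numeric(), stringsAsFactors = FALSE)
  on_chrom <- regions[regions$chrom == interval$chrom, , drop = FALSE]
  if (nrow(on_chrom) == 0L) return(empty)
  if (span_mode == "union_span") {
    on_chrom <- data.frame(chrom = interval$chrom,
                           start = min(on_chrom$start),
                           end = max(on_chrom$end), stringsAsFactors = FALSE)
  }
  start <- pmax(on_chrom$start, interval$phys_start)
  end <- pmin(on_chrom$end, interval$phys_end)
  keep <- start < end
  out <- data.frame(chrom = on_chrom$chrom[keep], start = start[keep],
                    end = end[keep], stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(empty)
  out$size_bp <- out$end - out$start
  rownames(out) <- NULL
  out
}
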