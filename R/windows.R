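#' Sliding-window genome scan
#'
#' Averages per-site statistics in overlapping windows along each
#' chromosome. Windows of width `window_bp` are anchored at position 1 and
#' advance by `step_bp` (defaults: 1 Mb windows, 10 kb step), the standard
#' smoothing for QTL-seq scans; the last window on a chromosome is the last
#' one whose start does not pass the final SNP. Each window averages,
#' unweighted, the non-missing per-site values whose position falls inside
#' it; windows holding fewer than `min_snps` sites are flagged missing
#' (`NA` means) so sparse windows cannot masquerade as signal.
#'
#' @param stats per-site statistics from [site_stats()], sorted by
#'   chromosome and position.
#' @param window_bp window width in bp (default 1e6).
#' @param step_bp step between window anchors in bp (default 1e4); must be
#'   positive. `window_bp < step_bp` is allowed (disjoint windows).
#' @param min_snps minimum sites for a window to be scored (default 1).
#' @return data frame with one row per window: `chrom`, `start`, `end`,
#'   `n_sites`, `mean_index_T`, `mean_index_S`, `mean_delta`, `mean_ed_k`.
#' @export
sliding_window <- function(stats, window_bp = 1e6, step_bp = 1e4, min_snps = 1L) {
  if (step_bp <= 0) stop("step_bp must be positive")
  if (window_bp <= 0) stop("window_bp must be positive")
  stat_cols <- c("mean_index_T" = "snp_index_T", "mean_index_S" = "snp_index_S",
                 "mean_delta" = "delta", "mean_ed_k" = "ed_k")
  out <- lapply(split(stats, stats$chrom), function(ch) {
    ch <- ch[order(ch$pos), , drop = FALSE]
    pos <- ch$pos
    starts <- seq(1, max(pos), by = step_bp)
    ends <- starts + window_bp - 1
    # windows indexed against the sorted positions via cumulative sums:
    # i0/i1 bracket the sites inside [start, end]
    i0 <- findInterval(starts - 1, pos)
    i1 <- findInterval(ends, pos)
    n_sites <- i1 - i0
    res <- data.frame(chrom = rep(ch$chrom[1L], length(starts)),
                      start = starts, end = ends, n_sites = n_sites,
                      stringsAsFactors = FALSE)
    for (j in seq_along(stat_cols)) {
      v <- ch[[stat_cols[[j]]]]
      ok <- !is.na(v)
      csum <- cumsum(c(0, ifelse(ok, v, 0)))
      cnum <- cumsum(c(0L, as.integer(ok)))
      nv <- cnum[i1 + 1L] - cnum[i0 + 1L]
      sv <- csum[i1 + 1L] - csum[i0 + 1L]
      res[[names(stat_cols)[j]]] <- ifelse(nv > 0, sv / nv, NA_real_)
    }
    res[res$n_sites < min_snps, names(stat_cols)] <- NA_real_
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "window_bp") <- window_bp
  attr(out, "step_bp") <- step_bp
  attr(out, "min_snps") <- min_snps
  out
}
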