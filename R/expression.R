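#' Relative expression by the 2^-ddCt method
#'
#' Normalizes target-gene qRT-PCR Ct values against a reference
#' (housekeeping) gene and a baseline time point within each series
#' (a series is one genotype x condition combination):
#' `dCt = Ct_target - Ct_reference` at each time,
#' `ddCt = dCt(time) - dCt(baseline)`, fold change `= 2^-ddCt`.
#' A ddCt of 0 is a fold change of 1; each PCR cycle is a doubling, so
#' `ddCt = -1` is a fold change of 2.
#'
#' By default (`mode = "mean_ct"`) replicate Ct values are averaged per
#' gene before dCt is formed — the convention when mean Ct values of the
#' biological replicates are normalized; `mode = "per_replicate"` pairs
#' target and reference by replicate first and averages the per-replicate
#' dCt. Replicate spread is reported as the SD of the per-replicate dCt
#' (requires matching replicate labels) and propagated on the ddCt scale
#' into `fold_lo`/`fold_hi` (= `2^-(ddCt +/- sd)`).
#'
#' @param records data frame with columns `genotype`, `condition`,
#'   `time_days`, `gene`, `ct` (> 0), `replicate`.
#' @param target_gene,reference_gene gene names in `records`.
#' @param baseline_time baseline time point (default 0); must be present
#'   for every series.
#' @param mode `"mean_ct"` (default) or `"per_replicate"`.
#' @return data frame with one row per (genotype, condition, time):
#'   `n_reps`, `delta_ct`, `sd_delta_ct`, `delta_delta_ct`, `fold_change`,
#'   `fold_lo`, `fold_hi`.
#' @export
relative_expression <- function(records, target_gene, reference_gene,
                                baseline_time = 0,
                                mode = c("mean_ct", "per_replicate")) {
  mode <- match.arg(mode)
  need <- c("genotype", "condition", "time_days", "gene", "ct", "replicate")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(records$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  records <- records[records$gene %in% c(target_gene, reference_gene), ,
                     drop = FALSE]
  key <- interaction(records$genotype, records$condition, records$time_days,
                     drop = TRUE)
  groups <- split(records, key)

  rows <- lapply(groups, function(g) {
    tg <- g[g$gene == target_gene, , drop = FALSE]
    rf <- g[g$gene == reference_gene, , drop = FALSE]
    out <- data.frame(genotype = g$genotype[1L], condition = g$condition[1L],
                      time_days = g$time_days[1L], stringsAsFactors = FALSE)
    if (nrow(rf) == 0L || nrow(tg) == 0L) {
      warning("no ", if (nrow(rf) == 0L) reference_gene else target_gene,
              " Ct for ", g$genotype[1L], "/", g$condition[1L], " day ",
              g$time_days[1L], "; point excluded")
      return(NULL)
    }
    paired <- merge(tg[, c("replicate", "ct")], rf[, c("replicate", "ct")],
                    by = "replicate", suffixes = c("_t", "_r"))
    dct_reps <- paired$ct_t - paired$ct_r
    out$n_reps <- nrow(tg)
    out$delta_ct <- if (mode == "mean_ct") mean(tg$ct) - mean(rf$ct) else
      mean(dct_reps)
    out$sd_delta_ct <- if (nrow(paired) >= 2L) sd(dct_reps) else NA_real_
    out
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(res) || nrow(res) == 0L) stop("no usable records")

  series <- interaction(res$genotype, res$condition, drop = TRUE)
  base_dct <- rep(NA_real_, nrow(res))
  for (s in levels(series)) {
    in_s <- series == s
    at_base <- in_s & res$time_days == baseline_time
    if (!any(at_base)) {
      stop("series ", s, " has no baseline time point (", baseline_time, ")")
    }
    base_dct[in_s] <- res$delta_ct[at_base][1L]
  }
  res$delta_delta_ct <- res$delta_ct - base_dct
  res$fold_change <- 2^(-res$delta_delta_ct)
  res$fold_lo <- 2^(-(res$delta_delta_ct + res$sd_delta_ct))
  res$fold_hi <- 2^(-(res$delta_delta_ct - res$sd_delta_ct))
  res <- res[order(res$genotype, res$condition, res$time_days), , drop = FALSE]
  rownames(res) <- NULL
  res
}
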