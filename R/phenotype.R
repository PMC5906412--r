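#' Descriptive statistics for a phenotype vector
#'
#' Conventions (recorded in the result): SD is the sample (n-1) standard
#' deviation; skewness is the adjusted Fisher-Pearson coefficient
#' `G1 = g1 * sqrt(n(n-1)) / (n-2)` with `g1 = m3 / m2^(3/2)`; kurtosis is
#' the bias-adjusted excess kurtosis
#' `G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3))` with `g2 = m4/m2^2 - 3`
#' (a normal sample has expectation 0). Skewness needs n >= 3 and kurtosis
#' n >= 4; below that, or for a constant vector, they are `NA`.
#'
#' @param values numeric vector, `NA`s dropped; needs n >= 2.
#' @return one-row data frame `n`, `mean`, `sd`, `min`, `max`, `skewness`,
#'   `kurtosis`, with attribute `"conventions"`.
#' @export
pheno_summary <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2L) stop("need at least two non-missing values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  skew <- NA_real_
  kurt <- NA_real_
  if (m2 > 0) {
    if (n >= 3L) {
      g1 <- m3 / m2^1.5
      skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
    }
    if (n >= 4L) {
      g2 <- m4 / m2^2 - 3
      kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    }
  }
  out <- data.frame(n = n, mean = m, sd = sd(x), min = min(x), max = max(x),
                    skewness = skew, kurtosis = kurt)
  attr(out, "conventions") <- c(
    sd = "sample (n-1)",
    skewness = "adjusted Fisher-Pearson G1",
    kurtosis = "bias-adjusted excess kurtosis G2 (normal => 0)")
  out
}

#' Two-sample comparison of parent phenotypes
#'
#' Student's two-sample t-test, equal variances by default (`var_equal =
#' FALSE` gives Welch). Significance stars follow the usual table
#' convention: `*` at p < 0.05, `**` at p < 0.01.
#'
#' @param values_a,values_b numeric vectors (n >= 2 each).
#' @param var_equal pool the variance estimate (default TRUE).
#' @return list `t`, `df`, `p`, `stars`, `mean_a`, `mean_b`, `method`;
#'   `t`/`p` are `NA` (flagged `degenerate = TRUE`) when both groups are
#'   constant.
#' @export
parent_comparison <- function(values_a, values_b, var_equal = TRUE) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  method <- if (var_equal) "student" else "welch"
  if (sd(a) == 0 && sd(b) == 0) {
    # no within-group variance: t is 0/0. Identical constants are reported
    # as no difference; separated constants as perfect separation.
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1, stars = "",
                  mean_a = mean(a), mean_b = mean(b), degenerate = TRUE,
                  method = method))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0, stars = "**",
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE,
                method = method))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  p <- tt$p.value
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = p,
       stars = stars, mean_a = mean(a), mean_b = mean(b), degenerate = FALSE,
       method = method)
}

#' Pairwise between-year Pearson correlations of a trait
#'
#' Pairs observations on line id within each pair of years and computes
#' Pearson's r with a two-sided test. Pairs with fewer than 3 complete
#' observations get `NA`.
#'
#' @param table long data frame with columns `ril_id`, `year`, `trait`,
#'   `value`.
#' @param trait trait to correlate (default `"PSST"`).
#' @return list of matrices `r`, `p`, `n` indexed by year.
#' @export
year_correlations <- function(table, trait = "PSST") {
  tab <- table[table$trait == trait, , drop = FALSE]
  if (any(duplicated(tab[, c("ril_id", "year")]))) {
    # replicate measurements are averaged before correlating years
    tab <- aggregate(value ~ ril_id + year, data = tab, FUN = mean)
  }
  years <- sort(unique(tab$year))
  k <- length(years)
  r <- matrix(NA_real_, k, k, dimnames = list(years, years))
  p <- r
  nmat <- matrix(0L, k, k, dimnames = list(years, years))
  diag(r) <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      xi <- tab[tab$year == years[i], c("ril_id", "value")]
      xj <- tab[tab$year == years[j], c("ril_id", "value")]
      mrg <- merge(xi, xj, by = "ril_id")
      nmat[i, j] <- nmat[j, i] <- nrow(mrg)
      if (nrow(mrg) >= 3L) {
        ct <- cor.test(mrg$value.x, mrg$value.y, method = "pearson")
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  list(r = r, p = p, n = nmat)
}

#' Group lines by haplotype at candidate SNP loci
#'
#' Lines are grouped by their exact allele string over the candidate loci.
#' The group matching the sensitive parent's haplotype is labelled `HapI`
#' and the tolerant parent's `HapII` (the conventional ordering when the
#' trait-raising parent is listed second); remaining groups are labelled
#' `HapIII`, `HapIV`, ... by descending size, ties broken by haplotype
#' string. Lines with a missing allele at any locus are excluded and
#' counted in the `"n_excluded"` attribute.
#'
#' @param genotypes data frame with a `ril_id` column and one column per
#'   candidate locus holding allele characters.
#' @param parent_hi_hap,parent_lo_hap allele vectors (or pre-joined
#'   strings) of the tolerant and sensitive parents over the same loci.
#' @param phenotypes named numeric vector of phenotypes (names = ril_id),
#'   or a data frame `ril_id`, `phenotype`.
#' @return data frame `label`, `haplotype`, `n`, `mean_phenotype`, with
#'   attribute `"members"` (named list of id vectors) and `"n_excluded"`.
#' @export
haplotype_groups <- function(genotypes, parent_hi_hap, parent_lo_hap,
                             phenotypes = NULL) {
  loci <- setdiff(names(genotypes), "ril_id")
  if (length(loci) == 0L) stop("no locus columns in genotypes")
  allele_mat <- as.matrix(genotypes[, loci, drop = FALSE])
  complete <- rowSums(is.na(allele_mat) | allele_mat == "") == 0L
  n_excluded <- sum(!complete)
  ids <- genotypes$ril_id[complete]
  haps <- apply(allele_mat[complete, , drop = FALSE], 1L, paste, collapse = "")
  hi_hap <- paste(parent_hi_hap, collapse = "")
  lo_hap <- paste(parent_lo_hap, collapse = "")
  if (hi_hap == lo_hap) stop("parental haplotypes are identical")

  members <- split(ids, haps)
  uniq <- names(members)
  label <- rep(NA_character_, length(uniq))
  label[uniq == lo_hap] <- "HapI"
  label[uniq == hi_hap] <- "HapII"
  rest <- which(is.na(label))
  rest <- rest[order(-lengths(members)[rest], uniq[rest])]
  if (length(rest) > 0L) {
    label[rest] <- paste0("Hap", as.character(utils::as.roman(2L + seq_along(rest))))
  }
  ord <- order(.roman_rank(label))
  phen <- NULL
  if (!is.null(phenotypes)) {
    if (is.data.frame(phenotypes)) {
      phen <- setNames(phenotypes$phenotype, phenotypes$ril_id)
    } else {
      phen <- phenotypes
    }
  }
  mean_phen <- vapply(members, function(m) {
    if (is.null(phen)) NA_real_ else mean(phen[m], na.rm = TRUE)
  }, numeric(1L))
  out <- data.frame(label = label, haplotype = uniq, n = lengths(members),
                    mean_phenotype = unname(mean_phen),
                    stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- members[out$haplotype]
  attr(out, "n_excluded") <- n_excluded
  out
}

.roman_rank <- function(labels) {
  as.integer(utils::as.roman(sub("^Hap", "", labels)))
}
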