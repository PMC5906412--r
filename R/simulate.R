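#' Synthetic genome map for RIL simulation
#'
#' Defines the coordinate frame the simulator works on: chromosome ids and
#' lengths, SNP site positions per chromosome, a uniform recombination
#' rate, and the (arbitrary, but fixed) base identities of the two parental
#' alleles at every site. The default — 12 chromosomes of 25 Mb with 2000
#' sites each — keeps a rice-like chromosome count at a site density small
#' enough for fast repeated simulation; the default recombination rate of
#' 7.85 cM/Mb gives the synthetic genome a total map length of about
#' 2355 cM, matching a dense biparental rice linkage map.
#'
#' @param n_chrom number of chromosomes (default 12).
#' @param chrom_length_bp chromosome length in bp (default 25e6), recycled.
#' @param sites_per_chrom SNP sites per chromosome (default 2000), recycled.
#' @param recomb_rate_cM_per_Mb uniform recombination rate (default 7.85).
#' @param seed seed controlling site placement and allele assignment.
#' @return object of class `"bsa_genome_map"`: list with `chromosomes`
#'   (data frame `chrom`, `length_bp`), `sites` (data frame `chrom`, `pos`,
#'   `hi_allele`, `lo_allele`, sorted, positions non-decreasing within
#'   chromosome) and `recomb_rate_cM_per_Mb`.
#' @export
genome_map <- function(n_chrom = 12L, chrom_length_bp = 25e6,
                       sites_per_chrom = 2000L,
                       recomb_rate_cM_per_Mb = 7.85, seed = 1L) {
  if (n_chrom < 1L) stop("need at least one chromosome")
  lens <- rep_len(chrom_length_bp, n_chrom)
  nsites <- rep_len(as.integer(sites_per_chrom), n_chrom)
  if (any(lens <= 0)) stop("chromosome lengths must be positive")
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  sites <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    pos <- sort(sample.int(lens[i], nsites[i]))
    hi <- sample(BASES, nsites[i], replace = TRUE)
    # lo drawn from the three remaining bases: sites stay parent-differentiating
    lo <- vapply(hi, function(b) sample(setdiff(BASES, b), 1L), character(1L))
    data.frame(chrom = chroms[i], pos = pos, hi_allele = hi, lo_allele = lo,
               stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL
  structure(list(chromosomes = data.frame(chrom = chroms, length_bp = lens,
                                          stringsAsFactors = FALSE),
                 sites = sites,
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb),
            class = "bsa_genome_map")
}

#' Build a genome map from explicit site positions
#'
#' Lower-level constructor for tests and custom layouts.
#'
#' @param sites data frame `chrom`, `pos` (non-decreasing within
#'   chromosome), optionally `hi_allele`, `lo_allele` (defaults G/A).
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   last site position per chromosome.
#' @param recomb_rate_cM_per_Mb uniform recombination rate.
#' @return `"bsa_genome_map"` object.
#' @export
genome_map_from_sites <- function(sites, chrom_lengths = NULL,
                                  recomb_rate_cM_per_Mb = 7.85) {
  if (is.null(sites$hi_allele)) sites$hi_allele <- "G"
  if (is.null(sites$lo_allele)) sites$lo_allele <- "A"
  for (ch in split(sites$pos, sites$chrom)) {
    if (is.unsorted(ch)) stop("site positions must be non-decreasing within chromosome")
  }
  chroms <- unique(sites$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(sites$pos, sites$chrom)[chroms], max, numeric(1L))
  }
  structure(list(chromosomes = data.frame(chrom = chroms,
                                          length_bp = unname(chrom_lengths[chroms]),
                                          stringsAsFactors = FALSE),
                 sites = sites[, c("chrom", "pos", "hi_allele", "lo_allele")],
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb),
            class = "bsa_genome_map")
}

# Crossover probability between adjacent sites from the map distance.
# d in Morgans. Haldane assumes no interference (and matches the
# independent-interval Markov chain below exactly); Kosambi's inverse,
# r = tanh(2d)/2, is offered for users who prefer its distance scale.
.adjacent_r <- function(pos, rate_cM_per_Mb, map_function = "haldane") {
  d <- diff(pos) / 1e6 * rate_cM_per_Mb / 100
  switch(map_function,
         haldane = 0.5 * (1 - exp(-2 * d)),
         kosambi = 0.5 * tanh(2 * d),
         stop("unknown map function: ", map_function))
}

# One meiosis for every individual at once on one chromosome.
# hapA/hapB: sites x individuals 0/1 matrices. Returns a gamete matrix:
# a Markov chain along sites chooses which parental haplotype to copy,
# switching between adjacent sites with the Haldane probability.
.gametes <- function(hapA, hapB, r) {
  n_sites <- nrow(hapA); n_ind <- ncol(hapA)
  start <- rbinom(n_ind, 1L, 0.5)
  if (n_sites == 1L) {
    choice <- matrix(start, 1L, n_ind)
  } else {
    switches <- matrix(rbinom((n_sites - 1L) * n_ind, 1L, rep(r, n_ind)),
                       n_sites - 1L, n_ind)
    choice <- apply(rbind(start, switches), 2L, cumsum) %% 2L
  }
  choice * hapA + (1L - choice) * hapB
}

#' Simulate a recombinant inbred line population by single seed descent
#'
#' Starts from the F1 of a biparental cross (heterozygous at every
#' parent-differentiating site) and selfs each line independently to the
#' requested generation, one seed per line per generation. Meioses
#' recombine under Haldane's map function (no crossover interference) at
#' the map's uniform rate. At the final generation lines are, by default,
#' idealized to full homozygosity: residual heterozygous sites (an expected
#' fraction `(1/2)^(g-1)` at generation `F_g`) are resolved to a random
#' homozygote, so pooled allele frequencies downstream are exact 0/1
#' dosages. Set `collapse_het = FALSE` to keep heterozygotes (dosage 0.5).
#'
#' @param map `"bsa_genome_map"` object.
#' @param n lines (default 190).
#' @param final_generation selfing generation of the returned lines
#'   (default 7, i.e. F7); must be >= 2.
#' @param seed integer seed; output is deterministic given the seed.
#' @param collapse_het idealize residual heterozygotes away (default TRUE).
#' @param map_function `"haldane"` (default, no interference) or
#'   `"kosambi"` for the crossover probability between adjacent sites.
#' @return object of class `"bsa_rils"`: list with `map`, `ids`, and
#'   `geno`, an `n x n_sites` matrix of tolerant-parent allele dosages
#'   (0, 0.5, 1), columns ordered as `map$sites`.
#' @export
simulate_rils <- function(map, n = 190L, final_generation = 7L, seed = 1L,
                          collapse_het = TRUE, map_function = "haldane") {
  if (n < 2L) stop("need at least two lines")
  if (final_generation < 2L) stop("final_generation must be >= 2 (F2 or later)")
  set.seed(seed)
  by_chrom <- split(seq_len(nrow(map$sites)), map$sites$chrom)
  # keep map order (split() sorts factor levels alphabetically)
  by_chrom <- by_chrom[unique(map$sites$chrom)]
  geno <- matrix(NA_real_, n, nrow(map$sites))
  for (idx in by_chrom) {
    pos <- map$sites$pos[idx]
    r <- .adjacent_r(pos, map$recomb_rate_cM_per_Mb, map_function)
    hapA <- matrix(1L, length(idx), n)  # F1: one chromosome from each parent
    hapB <- matrix(0L, length(idx), n)
    for (gen in seq_len(final_generation - 1L)) {
      g1 <- .gametes(hapA, hapB, r)
      g2 <- .gametes(hapA, hapB, r)
      hapA <- g1; hapB <- g2
    }
    dose <- (hapA + hapB) / 2
    if (collapse_het) {
      het <- which(hapA != hapB)
      if (length(het) > 0L) dose[het] <- rbinom(length(het), 1L, 0.5)
    }
    geno[, idx] <- t(dose)
  }
  structure(list(map = map, ids = sprintf("RIL%03d", seq_len(n)), geno = geno,
                 final_generation = final_generation,
                 phenotype = NULL),
            class = "bsa_rils")
}

#' Phenotype model with one planted additive QTL
#'
#' Defaults reproduce a cold-tolerance seed-set phenotype on the [0, 1]
#' scale: homozygote class means `grand_mean - additive_effect` (sensitive
#' parent allele) and `grand_mean + additive_effect` (tolerant parent
#' allele), i.e. 0.59 and 0.92 at the defaults, plus Gaussian noise.
#'
#' @param grand_mean phenotype midpoint (default 0.755).
#' @param qtl_chrom,qtl_pos planted locus; `qtl_pos = NA` resolves to the
#'   site nearest the chromosome midpoint at assignment time.
#' @param additive_effect half-difference between homozygote class means
#'   (default 0.165); positive means the tolerant-parent allele raises the
#'   phenotype.
#' @param noise_sd residual SD (default 0.05).
#' @param extra_qtls optional minor loci: data frame with columns `chrom`,
#'   `pos`, `effect` whose additive contributions stack on the major QTL
#'   (default none).
#' @return list of class `"bsa_phenotype_model"`.
#' @export
phenotype_model <- function(grand_mean = 0.755, qtl_chrom = "chr6",
                            qtl_pos = NA, additive_effect = 0.165,
                            noise_sd = 0.05, extra_qtls = NULL) {
  structure(list(grand_mean = grand_mean, qtl_chrom = qtl_chrom,
                 qtl_pos = qtl_pos, additive_effect = additive_effect,
                 noise_sd = noise_sd, extra_qtls = extra_qtls),
            class = "bsa_phenotype_model")
}

#' Assign phenotypes to simulated lines
#'
#' `phenotype = grand_mean + (2*dosage - 1) * additive_effect +
#' Normal(0, noise_sd)`, clamped to [0, 1]; `dosage` is the line's
#' tolerant-allele dosage at the planted QTL site.
#'
#' @param rils `"bsa_rils"` object.
#' @param model `"bsa_phenotype_model"`.
#' @param seed integer seed.
#' @return `rils` with `phenotype` set (named numeric vector) and
#'   `qtl_site` (resolved column index of the planted locus).
#' @export
assign_phenotypes <- function(rils, model = phenotype_model(), seed = 1L) {
  sites <- rils$map$sites
  on_chrom <- which(sites$chrom == model$qtl_chrom)
  if (length(on_chrom) == 0L) {
    stop("QTL chromosome ", model$qtl_chrom, " has no sites in the map")
  }
  if (is.na(model$qtl_pos)) {
    mid <- rils$map$chromosomes$length_bp[
      rils$map$chromosomes$chrom == model$qtl_chrom] / 2
    qtl_site <- on_chrom[which.min(abs(sites$pos[on_chrom] - mid))]
  } else {
    hit <- on_chrom[sites$pos[on_chrom] == model$qtl_pos]
    if (length(hit) == 0L) {
      stop("no site at ", model$qtl_chrom, ":", model$qtl_pos, " in the map")
    }
    qtl_site <- hit[1L]
  }
  set.seed(seed)
  dose <- rils$geno[, qtl_site]
  genetic <- (2 * dose - 1) * model$additive_effect
  if (!is.null(model$extra_qtls)) {
    for (q in seq_len(nrow(model$extra_qtls))) {
      hit <- which(sites$chrom == model$extra_qtls$chrom[q] &
                     sites$pos == model$extra_qtls$pos[q])
      if (length(hit) == 0L) {
        stop("no site at minor QTL ", model$extra_qtls$chrom[q], ":",
             model$extra_qtls$pos[q])
      }
      genetic <- genetic +
        (2 * rils$geno[, hit[1L]] - 1) * model$extra_qtls$effect[q]
    }
  }
  phen <- model$grand_mean + genetic + rnorm(length(dose), 0, model$noise_sd)
  phen <- pmin(pmax(phen, 0), 1)
  rils$phenotype <- setNames(phen, rils$ids)
  rils$qtl_site <- qtl_site
  rils$model <- model
  rils
}

#' Select the two extreme phenotype pools
#'
#' The tolerant pool takes the `n_per_pool` highest phenotypes among lines
#' at or above `hi_cutoff`; the sensitive pool takes the lowest among lines
#' at or below `lo_cutoff`. Ties are broken by line id. If fewer than
#' `n_per_pool` lines clear a cutoff the pool falls back, with a warning,
#' to the most extreme `n_per_pool` ranks regardless of the cutoff.
#'
#' @param rils `"bsa_rils"` with phenotypes assigned.
#' @param n_per_pool lines per pool (default 20).
#' @param hi_cutoff,lo_cutoff phenotype cutoffs (defaults 0.90 and 0.63).
#' @return list of class `"bsa_pools"` with elements `T` and `S` (character
#'   id vectors) and the selection parameters.
#' @export
build_pools <- function(rils, n_per_pool = 20L, hi_cutoff = 0.90,
                        lo_cutoff = 0.63) {
  phen <- rils$phenotype
  if (is.null(phen)) stop("assign phenotypes before building pools")
  if (2L * n_per_pool > length(phen)) stop("pools larger than the population")
  ids <- names(phen)
  # ties resolve from opposite ends of the id order so the two pools can
  # never collide even on a constant phenotype
  ord_hi <- ids[order(-phen, xtfrm(ids))]
  ord_lo <- ids[order(phen, -xtfrm(ids))]
  hi_ok <- ord_hi[phen[ord_hi] >= hi_cutoff]
  lo_ok <- ord_lo[phen[ord_lo] <= lo_cutoff]
  if (length(hi_ok) < n_per_pool) {
    warning("only ", length(hi_ok), " lines at or above ", hi_cutoff,
            "; taking the top ", n_per_pool, " ranks")
    pool_T <- ord_hi[seq_len(n_per_pool)]
  } else {
    pool_T <- hi_ok[seq_len(n_per_pool)]
  }
  if (length(lo_ok) < n_per_pool) {
    warning("only ", length(lo_ok), " lines at or below ", lo_cutoff,
            "; taking the bottom ", n_per_pool, " ranks")
    pool_S <- ord_lo[seq_len(n_per_pool)]
  } else {
    pool_S <- lo_ok[seq_len(n_per_pool)]
  }
  stopifnot(length(intersect(pool_T, pool_S)) == 0L)
  structure(list(T = pool_T, S = pool_S, n_per_pool = n_per_pool,
                 hi_cutoff = hi_cutoff, lo_cutoff = lo_cutoff),
            class = "bsa_pools")
}

#' Sample pooled sequencing reads for one pool
#'
#' Emulates equal-contribution DNA pooling read out by short-read
#' sequencing: at every site the latent pool allele frequency is the mean
#' tolerant-allele dosage over pool members, the site's read depth is
#' Poisson(`mean_depth`), and the tolerant-allele read count is
#' Binomial(depth, frequency). Counts land on the site's two parental
#' bases; a depth of 0 leaves all four counts zero, which downstream
#' statistics treat as missing for that pool.
#'
#' @param pool character vector of member ids (or a `"bsa_pools"` element).
#' @param rils `"bsa_rils"` object holding the members' genotypes.
#' @param mean_depth mean reads per site (> 0).
#' @param label `"T"` or `"S"`: which pool's count columns to fill (the
#'   other pool's columns are zero).
#' @param seed integer seed.
#' @return site data frame (see [validate_sites()]) with this pool's
#'   counts filled in.
#' @export
sample_pool_reads <- function(pool, rils, mean_depth, label = c("T", "S"),
                              seed = 1L) {
  label <- match.arg(label)
  if (mean_depth <= 0) stop("mean_depth must be positive")
  members <- if (is.character(pool)) pool else pool[[label]]
  rows <- match(members, rils$ids)
  if (any(is.na(rows))) stop("pool contains ids absent from the population")
  set.seed(seed)
  p <- colMeans(rils$geno[rows, , drop = FALSE])
  n_sites <- length(p)
  depth <- rpois(n_sites, mean_depth)
  n_hi <- rbinom(n_sites, depth, p)
  sites <- rils$map$sites
  out <- sites[, c("chrom", "pos", "hi_allele", "lo_allele")]
  for (col in SITE_COUNT_COLS) out[[col]] <- 0L
  pre <- paste0(label, "_")
  hi_col <- paste0(pre, sites$hi_allele)
  lo_col <- paste0(pre, sites$lo_allele)
  for (b in BASES) {
    col <- paste0(pre, b)
    out[[col]] <- ifelse(hi_col == col, n_hi, 0L) +
      ifelse(lo_col == col, depth - n_hi, 0L)
  }
  rownames(out) <- NULL
  out
}

#' Combine single-pool read draws into one site table
#'
#' @param t_sites,s_sites outputs of [sample_pool_reads()] for the tolerant
#'   and sensitive pools over the same map.
#' @return site data frame with both pools' counts.
#' @export
combine_pool_reads <- function(t_sites, s_sites) {
  stopifnot(identical(t_sites$chrom, s_sites$chrom),
            identical(t_sites$pos, s_sites$pos))
  out <- t_sites
  for (col in paste0("S_", BASES)) out[[col]] <- s_sites[[col]]
  validate_sites(out)
  out
}

#' Simulate a complete extreme-pool sequencing experiment
#'
#' Chains the simulator end to end: RIL population by single seed descent,
#' phenotypes under a one-QTL additive model, extreme-pool selection, and
#' pooled read counts for both pools. Defaults reproduce the design this
#' package targets: 190 F7 lines, pools of 20 selected at phenotype
#' cutoffs 0.90 / 0.63, and mean depths of 31x (tolerant) and 45x
#' (sensitive).
#'
#' @param map `"bsa_genome_map"` (default [genome_map()]).
#' @param n_rils population size (default 190).
#' @param final_generation selfing generation (default 7).
#' @param model phenotype model (default [phenotype_model()]).
#' @param n_per_pool,hi_cutoff,lo_cutoff pool design (defaults 20, 0.90,
#'   0.63).
#' @param depth_T,depth_S mean pool depths (defaults 31, 45).
#' @param seed master seed; stage seeds are derived from it, so the whole
#'   experiment is deterministic given `seed`.
#' @return list with `sites` (combined site table), `rils`, `pools`, and
#'   `truth` (planted QTL chromosome, position, site index and effect).
#' @export
simulate_bsa_experiment <- function(map = genome_map(), n_rils = 190L,
                                    final_generation = 7L,
                                    model = phenotype_model(),
                                    n_per_pool = 20L, hi_cutoff = 0.90,
                                    lo_cutoff = 0.63, depth_T = 31,
                                    depth_S = 45, seed = 1L) {
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 4L)
  rils <- simulate_rils(map, n = n_rils, final_generation = final_generation,
                        seed = stage_seeds[1L])
  rils <- assign_phenotypes(rils, model, seed = stage_seeds[2L])
  pools <- build_pools(rils, n_per_pool = n_per_pool, hi_cutoff = hi_cutoff,
                       lo_cutoff = lo_cutoff)
  t_sites <- sample_pool_reads(pools$T, rils, depth_T, "T",
                               seed = stage_seeds[3L])
  s_sites <- sample_pool_reads(pools$S, rils, depth_S, "S",
                               seed = stage_seeds[4L])
  sites <- combine_pool_reads(t_sites, s_sites)
  list(sites = sites, rils = rils, pools = pools,
       truth = list(qtl_chrom = map$sites$chrom[rils$qtl_site],
                    qtl_pos = map$sites$pos[rils$qtl_site],
                    qtl_site = rils$qtl_site,
                    additive_effect = model$additive_effect),
       seed = seed)
}
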