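#' Default pipeline configuration
#'
#' Returns the full set of tunables with their defaults; any subset can be
#' overridden via `...` or by a YAML config file passed to
#' [run_pipeline()]. Numeric tunables are validated against the
#' preconditions of the operations that consume them before any stage
#' runs.
#'
#' @param ... named overrides.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    # input: path to a site TSV, or NULL to simulate
    sites = NULL,
    genes = NULL,          # optional GFF3 of gene models
    markers = NULL,        # optional marker TSV (name chrom start end)
    left_marker = NULL,    # flanking marker names for the QTL interval
    right_marker = NULL,
    # scan
    window_bp = 1e6, step_bp = 1e4, power = 5, min_depth = 4L, min_snps = 1L,
    confidence = 0.99, n_sims = 10000L,
    merge_gap_bp = NULL, boundary_rounding = 1e4,
    ed_multiplier = 3, ed_sd_type = "sample",
    # simulation (used when sites is NULL)
    n_rils = 190L, final_generation = 7L, n_per_pool = 20L,
    hi_cutoff = 0.90, lo_cutoff = 0.63, depth_T = 31, depth_S = 45,
    n_chrom = 12L, chrom_length_bp = 25e6, sites_per_chrom = 2000L,
    recomb_rate_cM_per_Mb = 7.85,
    grand_mean = 0.755, additive_effect = 0.165, noise_sd = 0.05,
    qtl_chrom = "chr6", qtl_pos = NA,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

validate_config <- function(cfg) {
  if (cfg$step_bp <= 0) stop("config error: step_bp must be positive")
  if (cfg$window_bp <= 0) stop("config error: window_bp must be positive")
  if (cfg$n_sims < 1L) stop("config error: n_sims must be >= 1")
  if (cfg$confidence <= 0 || cfg$confidence >= 1) {
    stop("config error: confidence must be in (0, 1)")
  }
  if (is.null(cfg$sites)) {
    if (cfg$n_rils < 2L) stop("config error: n_rils must be >= 2")
    if (cfg$final_generation < 2L) stop("config error: final_generation must be >= 2")
    if (cfg$depth_T <= 0 || cfg$depth_S <= 0) {
      stop("config error: pool depths must be positive")
    }
    if (2L * cfg$n_per_pool > cfg$n_rils) {
      stop("config error: pools larger than the population")
    }
  }
  invisible(cfg)
}

#' Run the full association-scan pipeline
#'
#' Orchestrates simulate/load -> per-site statistics -> sliding-window scan
#' -> null CI and ED threshold -> region calling (both statistics) ->
#' optional gene counting and QTL-interval intersection, writing every
#' stage's table plus a JSON manifest to `out_dir`. Given the same
#' configuration and seed the written outputs are bit-identical across
#' runs.
#'
#' @param config list from [default_config()], a named list of overrides,
#'   or a path to a YAML file of overrides.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `status` (0 on success), `out_dir`, and
#'   the in-memory stage results (`sites`, `stats`, `windows`, `ci`,
#'   `ed_thr`, `regions_ed`, `regions_delta`, `intersection`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- do.call(default_config, config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  outputs <- character()
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, name)
    path
  }

  truth <- NULL
  if (is.null(config$sites)) {
    logf("simulating extreme-pool experiment (seed ", config$seed, ")")
    map <- genome_map(n_chrom = config$n_chrom,
                      chrom_length_bp = config$chrom_length_bp,
                      sites_per_chrom = config$sites_per_chrom,
                      recomb_rate_cM_per_Mb = config$recomb_rate_cM_per_Mb,
                      seed = config$seed)
    model <- phenotype_model(grand_mean = config$grand_mean,
                             qtl_chrom = config$qtl_chrom,
                             qtl_pos = config$qtl_pos,
                             additive_effect = config$additive_effect,
                             noise_sd = config$noise_sd)
    sim <- simulate_bsa_experiment(map, n_rils = config$n_rils,
                                   final_generation = config$final_generation,
                                   model = model,
                                   n_per_pool = config$n_per_pool,
                                   hi_cutoff = config$hi_cutoff,
                                   lo_cutoff = config$lo_cutoff,
                                   depth_T = config$depth_T,
                                   depth_S = config$depth_S,
                                   seed = config$seed)
    sites <- sim$sites
    truth <- sim$truth
    emit(sites, "sites.tsv", write_tsv_sites)
    phen <- data.frame(ril_id = sim$rils$ids,
                       phenotype = unname(sim$rils$phenotype),
                       pool = ifelse(sim$rils$ids %in% sim$pools$T, "T",
                                     ifelse(sim$rils$ids %in% sim$pools$S, "S", "")))
    emit(phen, "phenotypes.tsv", function(x, p)
      write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit(truth, "truth.json", function(x, p)
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA))
  } else {
    logf("reading sites from ", config$sites)
    sites <- read_tsv_sites(config$sites)
  }

  logf("computing per-site statistics (", nrow(sites), " sites)")
  stats <- site_stats(sites, k = config$power, min_depth = config$min_depth)
  emit(stats, "site_stats.tsv", function(x, p)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE))

  logf("sliding-window scan (window ", config$window_bp, " bp, step ",
       config$step_bp, " bp)")
  windows <- sliding_window(stats, window_bp = config$window_bp,
                            step_bp = config$step_bp,
                            min_snps = config$min_snps)
  emit(windows, "windows.tsv", function(x, p)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE))

  logf("null confidence interval and ED threshold")
  depth_T <- round(mean(stats$depth_T[stats$depth_T > 0]))
  depth_S <- round(mean(stats$depth_S[stats$depth_S > 0]))
  ci <- null_ci(pool_size = config$n_per_pool, depth_T = max(1, depth_T),
                depth_S = max(1, depth_S), confidence = config$confidence,
                n_sims = config$n_sims, seed = config$seed)
  ed_thr <- ed_threshold(windows, multiplier = config$ed_multiplier,
                         sd_type = config$ed_sd_type)

  regions_ed <- call_regions(windows, ed_thr, stat = "mean_ed_k",
                             strict = FALSE,
                             merge_gap_bp = config$merge_gap_bp,
                             boundary_rounding = config$boundary_rounding)
  regions_delta <- call_regions(windows, ci$upper, stat = "mean_delta",
                                strict = TRUE,
                                merge_gap_bp = config$merge_gap_bp,
                                boundary_rounding = config$boundary_rounding)
  logf(nrow(regions_ed), " ED^k regions; ", nrow(regions_delta),
       " delta(SNP-index) regions")

  if (!is.null(config$genes)) {
    genes <- read_gff3_genes(config$genes)
    regions_ed$gene_count <- count_genes(regions_ed, genes)
    regions_delta$gene_count <- count_genes(regions_delta, genes)
  }
  emit(regions_ed, "regions_ed.tsv", write_regions_table)
  emit(regions_delta, "regions_delta.tsv", write_regions_table)
  emit(regions_ed, "regions_ed.bed", write_regions_bed)
  emit(regions_delta, "regions_delta.bed", write_regions_bed)

  intersection <- NULL
  if (!is.null(config$markers) && !is.null(config$left_marker)) {
    markers <- read_markers_tsv(config$markers)
    left <- markers[markers$name == config$left_marker, ]
    right <- markers[markers$name == config$right_marker, ]
    if (nrow(left) != 1L || nrow(right) != 1L) {
      stop("flanking markers not found in ", config$markers)
    }
    interval <- qtl_physical_interval(as.list(left), as.list(right),
                                      convention = "left_starts")
    intersection <- intersect_with_interval(regions_delta, interval,
                                            span_mode = "union_span")
    emit(intersection, "intersection.tsv", function(x, p)
      write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  manifest <- list(
    package = "bsascan",
    version = as.character(packageVersion("bsascan")),
    config = config[!vapply(config, is.null, logical(1L))],
    inputs = Filter(Negate(is.null),
                    list(sites = config$sites, genes = config$genes,
                         markers = config$markers)),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)),
    null_ci = list(lower = ci$lower, upper = ci$upper,
                   confidence = ci$confidence, depth_T = ci$depth_T,
                   depth_S = ci$depth_S),
    ed_threshold = list(value = as.numeric(ed_thr),
                        method = attr(ed_thr, "method")),
    status = "ok")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete; manifest written")

  invisible(list(status = 0L, out_dir = out_dir, sites = sites, stats = stats,
                 windows = windows, ci = ci, ed_thr = ed_thr,
                 regions_ed = regions_ed, regions_delta = regions_delta,
                 intersection = intersection, truth = truth,
                 manifest = manifest))
}
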