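test_that("ed_threshold follows the mean-plus-SD rule", {
  const <- windows_frame("chr1", 1, 100, ed_k = rep(2.5, 12))
  expect_equal(as.numeric(ed_threshold(const)), 2.5)

  w <- windows_frame("chr1", 1, 100, ed_k = c(0, 0, 0, 0, 10))
  thr <- suppressWarnings(
    ed_threshold(w, multiplier = 3, sd_type = "population"))
  expect_equal(as.numeric(thr), 2 + 3 * 4)  # mean 2, population SD 4

  shuffled <- w[c(5, 2, 4, 1, 3), ]
  expect_equal(as.numeric(suppressWarnings(
    ed_threshold(shuffled, multiplier = 3, sd_type = "population"))),
    as.numeric(thr))

  all_na <- windows_frame("chr1", 1, 100, ed_k = rep(NA_real_, 5))
  expect_error(ed_threshold(all_na), "missing")
})

test_that("region calling unions significant windows, merges and rounds", {
  w <- data.frame(chrom = "chr1",
                  start = c(1, 10001, 20001, 40001, 100001),
                  end = c(30000, 40000, 50000, 70000, 130000),
                  n_sites = 5L,
                  mean_ed_k = c(5, 5, 1, 5, 5))
  attr(w, "step_bp") <- 10000
  regions <- call_regions(w, threshold = 5, boundary_rounding = 10000)
  # windows 1,2 and 4 overlap -> one run to 70000; window 5 separated by
  # 30000 > step -> second region
  expect_equal(nrow(regions), 2L)
  expect_equal(regions$start, c(0, 100000))
  expect_equal(regions$end, c(70000, 130000))
  expect_equal(regions$size_bp, regions$end - regions$start)

  # a window exactly at the threshold counts under >= but not under strict
  at_thr <- call_regions(w, threshold = 5, strict = TRUE)
  expect_equal(nrow(at_thr), 0L)

  none <- call_regions(w, threshold = 99)
  expect_equal(nrow(none), 0L)
})

test_that("merging is idempotent and respects the gap parameter", {
  iv <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                   start = c(100, 250, 900, 10),
                   end = c(200, 300, 1000, 20))
  m1 <- merge_regions(iv, merge_gap_bp = 50)
  expect_equal(m1$start[m1$chrom == "chr1"], c(100, 900))
  expect_equal(m1$end[m1$chrom == "chr1"], c(300, 1000))
  expect_identical(merge_regions(m1, merge_gap_bp = 50), m1)
  # wide enough gap bridges everything on chr1
  m2 <- merge_regions(iv, merge_gap_bp = 600)
  expect_equal(nrow(m2[m2$chrom == "chr1", ]), 1L)
})

test_that("published ED-method region table sums to 23.48 Mb", {
  regions <- read.delim(extdata("ed_regions.tsv"))
  regions <- merge_regions(regions)  # already disjoint; normalizes sorting
  regions$size_bp <- regions$end - regions$start
  expect_equal(nrow(regions), 6L)
  expect_equal(sum(regions$size_bp) / 1e6, 23.48, tolerance = 1e-9)
})

test_that("published SNP-index-method region table sums to 3.68 Mb", {
  regions <- read.delim(extdata("snpindex_regions.tsv"))
  regions <- merge_regions(regions)
  regions$size_bp <- regions$end - regions$start
  expect_equal(nrow(regions), 6L)
  expect_equal(sum(regions$size_bp) / 1e6, 3.68, tolerance = 1e-9)
})

test_that("gene counting matches the quadratic oracle", {
  genes <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(50, 150, 190), end = c(99, 160, 300))
  region <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_equal(count_genes(region, genes), 2L)
  expect_equal(count_genes(region, genes[0, ]), 0L)

  set.seed(77)
  n <- 1000
  rgenes <- data.frame(gene_id = paste0("g", 1:n),
                       chrom = sample(c("chr1", "chr2"), n, TRUE),
                       start = sample.int(1e6, n, TRUE))
  rgenes$end <- rgenes$start + sample.int(5000, n, TRUE)
  rregions <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                         start = sample.int(1e6, 50, TRUE))
  rregions$end <- rregions$start + sample.int(50000, 50, TRUE)
  got <- count_genes(rregions, rgenes)
  oracle <- vapply(seq_len(50), function(i) {
    sum(rgenes$chrom == rregions$chrom[i] &
          rgenes$start <= rregions$end[i] &
          rgenes$end >= rregions$start[i])
  }, numeric(1L))
  expect_equal(as.numeric(got), oracle)
})

test_that("marker pairs define the QTL physical interval", {
  markers <- read_markers_tsv(extdata("ssr_markers.tsv"))
  left <- as.list(markers[markers$name == "RM20261", ])
  right <- as.list(markers[markers$name == "RM20356", ])

  outer <- qtl_physical_interval(left, right, convention = "outer")
  expect_equal(outer$span_bp, 2349480)
  expect_equal(outer$span_bp / 1e6, 2.35, tolerance = 0.001)

  edge <- qtl_physical_interval(left, right, convention = "left_starts")
  expect_equal(edge$span_bp, 23654188 - 21304727)
  expect_equal(edge$span_bp, 2349461)

  expect_error(qtl_physical_interval(left, left), "upstream")
  off <- right
  off$chrom <- "chr7"
  expect_error(qtl_physical_interval(left, off), "different chromosomes")
})

test_that("union-span intersection reproduces the refined 1.81 Mb interval", {
  regions <- read.delim(extdata("snpindex_regions.tsv"))
  regions <- regions[regions$chrom == "chr6", ]
  markers <- read_markers_tsv(extdata("ssr_markers.tsv"))
  interval <- qtl_physical_interval(
    as.list(markers[markers$name == "RM20261", ]),
    as.list(markers[markers$name == "RM20356", ]),
    convention = "left_starts")

  hit <- intersect_with_interval(regions, interval, span_mode = "union_span")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 21840000)
  expect_equal(hit$end, 23654188)
  expect_equal(hit$size_bp, 1814188)
  expect_equal(hit$size_bp / 1e6, 1.81, tolerance = 0.005)

  strict <- intersect_with_interval(regions, interval, span_mode = "strict")
  expect_equal(nrow(strict), 2L)
  expect_equal(strict$start, c(21840000, 22140000))
  expect_equal(strict$end, c(22070000, 23654188))
  expect_equal(sum(strict$size_bp), 1744188)
})

test_that("intersection handles containment and disjoint inputs", {
  regions <- data.frame(chrom = "chr1", start = c(100, 400), end = c(200, 500))
  interval <- list(chrom = "chr1", phys_start = 1, phys_end = 1000)
  hit <- intersect_with_interval(regions, interval, span_mode = "union_span")
  expect_equal(c(hit$start, hit$end), c(100, 500))

  far <- list(chrom = "chr1", phys_start = 5000, phys_end = 6000)
  expect_equal(nrow(intersect_with_interval(regions, far)), 0L)
  other <- list(chrom = "chr9", phys_start = 1, phys_end = 1000)
  expect_equal(nrow(intersect_with_interval(regions, other)), 0L)
})
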