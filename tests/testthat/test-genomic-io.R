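write_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("sample sheets parse, canonicalize and validate", {
  path <- write_lines(c(
    "sample_id\tmark\tgenotype\tage_months\treplicate\tfraction",
    "s1\tH3K27ac\twt\t6.0\t1\tNeuN+",
    "s2\tH3K27ac\tHD\t6\t1\tNeuN+",
    "s3\tH3K27me3\tWT\t10\t2\tbulk"))
  sheet <- read_sample_sheet(path)
  expect_identical(nrow(sheet), 3L)
  expect_identical(sheet$genotype, c("WT", "HD", "WT"))
  expect_identical(sheet$age_months, c(6, 6, 10))

  dup <- write_lines(c(
    "sample_id\tmark\tgenotype\tage_months\treplicate\tfraction",
    "s1\tH3K27ac\tWT\t6\t1\tNeuN+",
    "s1\tH3K27ac\tHD\t6\t1\tNeuN+"))
  expect_error(read_sample_sheet(dup), "s1")

  bad_age <- write_lines(c(
    "sample_id\tmark\tgenotype\tage_months\treplicate\tfraction",
    "s1\tH3K27ac\tWT\tsix\t1\tNeuN+"))
  expect_error(read_sample_sheet(bad_age), "age")

  no_col <- write_lines(c("sample_id\tmark\tgenotype\tage_months\treplicate",
                          "s1\tH3K27ac\tWT\t6\t1"))
  expect_error(read_sample_sheet(no_col), "fraction")
})

test_that("BED parsing fills defaults, keeps 0-based coordinates and
           round-trips", {
  bed6 <- write_lines(c("track name=test",
                        "chr1\t100\t200\tgeneA\t0\t+"))
  regions <- read_regions_bed(bed6)
  expect_identical(regions$start, 100)
  expect_identical(regions$end, 200)
  expect_identical(regions$name, "geneA")
  expect_identical(regions$strand, "+")
  # BED3: name and strand fall back to defaults
  bed3 <- write_lines("chr1\t300\t400")
  r3 <- read_regions_bed(bed3)
  expect_identical(r3$name, "chr1:300-400")
  expect_identical(r3$strand, ".")

  bad <- write_lines("chr1\t200\t100")
  expect_error(read_regions_bed(bad), "malformed BED")

  # BED6 round trip
  out <- withr::local_tempfile(fileext = ".bed")
  orig <- data.frame(chrom = c("chr2", "chr1"), start = c(0, 50),
                     end = c(10, 500), name = c("a", "b"), score = c(1, 2.5),
                     strand = c("-", "+"))
  write_regions_bed(orig, out)
  back <- read_regions_bed(out)
  expect_identical(back$start, orig$start)
  expect_identical(back$end, orig$end)
  expect_identical(back$name, orig$name)
  expect_identical(back$score, orig$score)
  expect_identical(back$strand, orig$strand)
})

test_that("promoter windows follow the strand-aware half-open rule", {
  genes <- data.frame(chrom = "chr1", start = c(1000, 1000, 100),
                      end = c(5000, 5000, 5000), name = c("p", "m", "clip"),
                      score = 0, strand = c("+", "-", "+"))
  prom <- promoters_from_genes(genes, upstream = 500, downstream = 500)
  expect_identical(prom$start, c(500, 4500, 0))
  expect_identical(prom$end, c(1500, 5500, 600))
  expect_identical(prom$name, c("p_promoter", "m_promoter", "clip_promoter"))
  # promoter length = upstream + downstream unless clipped at 0
  expect_identical(prom$end[1] - prom$start[1], 1000)
  expect_error(promoters_from_genes(genes, 0, 0), "both 0")
  expect_error(promoters_from_genes(genes[0, ], 500, 500), "empty")
})

test_that("bedGraph region coverage matches a base-by-base oracle", {
  bg <- write_lines(c("chr1\t0\t100\t2",
                      "chr1\t50\t150\t4",
                      "chr2\t10\t20\t1.5"))
  regions <- data.frame(chrom = c("chr1", "chr1", "chr3"),
                        start = c(0, 0, 0), end = c(100, 100, 50),
                        name = c("full", "partial", "empty"),
                        strand = c("+", "+", "+"), score = 0)
  # full-overlap and spec worked example: interval [50,150) value 4 over
  # region [0,100) contributes 4 * 50
  sums <- suppressWarnings(
    region_coverage_from_bedgraph(bg, regions, mode = "sum"))
  expect_equal(unname(sums), c(2 * 100 + 4 * 50, 2 * 100 + 4 * 50, 0))
  means <- suppressWarnings(
    region_coverage_from_bedgraph(bg, regions, mode = "mean"))
  expect_equal(unname(means[1]), 4)

  # brute-force per-base oracle on random intervals
  set.seed(1)
  iv <- data.frame(start = sample(0:80, 12), width = sample(1:30, 12,
                                                            replace = TRUE),
                   value = round(runif(12, 0, 5), 2))
  iv$end <- iv$start + iv$width
  bg2 <- write_lines(sprintf("chr1\t%d\t%d\t%g", iv$start, iv$end, iv$value))
  base <- numeric(200)
  for (i in seq_len(nrow(iv)))
    base[(iv$start[i] + 1):iv$end[i]] <-
      base[(iv$start[i] + 1):iv$end[i]] + iv$value[i]
  reg2 <- data.frame(chrom = "chr1", start = c(0, 25, 90),
                     end = c(200, 60, 91), name = c("r1", "r2", "r3"),
                     score = 0, strand = "+")
  got <- suppressWarnings(region_coverage_from_bedgraph(bg2, reg2, "sum"))
  want <- c(sum(base), sum(base[26:60]), base[91])
  expect_equal(unname(got), want)
  # additivity over disjoint sub-regions
  halves <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                       name = c("h1", "h2"), score = 0, strand = "+")
  parts <- suppressWarnings(region_coverage_from_bedgraph(bg2, halves, "sum"))
  expect_equal(sum(parts), sum(base))
})

test_that("binned signal matches per-base averaging and is strand-oriented", {
  # constant field: every bin equals the constant
  bgc <- write_lines("chr1\t0\t10000\t3")
  reg <- data.frame(chrom = "chr1", start = 4000, end = 6000, name = "g",
                    score = 0, strand = "+")
  b <- bin_region_signal(bgc, reg, bin_scheme_tss(flank = 1000,
                                                  bin_width = 100))
  expect_equal(unname(b[1, ]), rep(3, 20))

  # step around the TSS vs brute-force per-base means
  bgs <- write_lines(c("chr1\t3900\t4000\t1", "chr1\t4000\t4300\t5"))
  scheme <- bin_scheme_tss(flank = 200, bin_width = 50)
  b2 <- bin_region_signal(bgs, reg, scheme)
  base <- numeric(12000)
  base[3901:4000] <- 1
  base[4001:4300] <- 5
  want <- colMeans(matrix(base[3801:4200], nrow = 50))
  expect_equal(unname(b2[1, ]), want)

  # minus-strand twin is the reverse of its plus twin
  two <- data.frame(chrom = "chr1", start = c(4000, 2000),
                    end = c(6000, 4000), name = c("plus", "minus"), score = 0,
                    strand = c("+", "-"))
  bga <- write_lines(sprintf("chr1\t%d\t%d\t%g", seq(0, 11800, 200),
                             seq(200, 12000, 200), seq(0.1, 6, 0.1)))
  sch <- bin_scheme_body(flank = 400, n_body_bins = 10,
                         flank_bin_width = 200)
  bb <- bin_region_signal(bga, two, sch)
  # the minus gene spans the mirror-image window; with a linear gradient its
  # profile is the reverse of the plus gene's profile
  grad_plus <- bb["plus", ]
  expect_true(all(diff(grad_plus) > 0))
  expect_true(all(diff(bb["minus", ]) < 0))
})

test_that("count matrices and GMT collections round-trip with validation", {
  m <- matrix(c(0, 5, 4, 4), 2, 2,
              dimnames = list(c("r1", "r2"), c("s1", "s2")))
  cm <- count_matrix(m, mark = "H3K27ac")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, path)
  expect_identical(read_count_matrix(path, mark = "H3K27ac")$counts,
                   cm$counts)
  expect_error(count_matrix(matrix(-1, 1, 1, dimnames = list("r", "s"))),
               "negative")
  expect_error(count_matrix(matrix(1.5, 1, 1, dimnames = list("r", "s"))),
               "non-integer")

  gmt <- write_lines(c("S1\tdesc\ta\tb\ta", "S2\tother\tc"))
  sets <- read_gmt(gmt)
  expect_identical(sets$S1, c("a", "b"))  # dedup, order preserved
  expect_identical(sets$S2, "c")
  bad <- write_lines("S1\tonly-two-fields")
  expect_error(read_gmt(bad), "fewer than 3")

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(list(A = c("x", "y"), B = "z"), out,
            descriptions = c(A = "setA", B = "setB"))
  back <- read_gmt(out)
  expect_identical(back$A, c("x", "y"))
  expect_identical(attr(back, "descriptions")[["A"]], "setA")
})
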