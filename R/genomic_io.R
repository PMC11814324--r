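## Genomic I/O: sample sheets, BED regions, bedGraph coverage, binned
## signal, TSV matrices and GMT gene sets. All coordinates are 0-based
## half-open (BED convention); the only conversion point is the bridge to
## GRanges (1-based closed), localized in regions_to_granges().

VALID_FRACTIONS <- c("NeuN+", "NeuN-", "bulk")

#' Read and validate a sample sheet
#'
#' The sheet is a TSV with header and the six columns `sample_id`, `mark`,
#' `genotype`, `age_months`, `replicate`, `fraction`. It drives all grouping
#' and H3K27ac/H3K27me3 pairing downstream.
#'
#' @param path TSV file path.
#' @return A validated data.frame with canonicalized `genotype` (`WT`/`HD`)
#'   and `fraction` (`NeuN+`, `NeuN-`, `bulk`), numeric `age_months` and
#'   integer `replicate`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("sample_id", "mark", "genotype", "age_months", "replicate",
                "fraction")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(dup), collapse = ", "))
  age <- suppressWarnings(as.numeric(df$age_months))
  if (anyNA(age))
    stop("unparseable age_months value(s): ",
         paste(df$age_months[is.na(age)], collapse = ", "))
  df$age_months <- age
  df$genotype <- toupper(trimws(df$genotype))
  if (!all(df$genotype %in% c("WT", "HD")))
    stop("genotype must be WT or HD")
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$replicate)) stop("unparseable replicate value(s)")
  frac <- trimws(df$fraction)
  frac[tolower(frac) == "bulk"] <- "bulk"
  if (!all(frac %in% VALID_FRACTIONS))
    stop("fraction must be one of: ", paste(VALID_FRACTIONS, collapse = ", "))
  df$fraction <- frac
  if (anyNA(df) || any(df == ""))
    stop("sample sheet has incomplete records")
  df
}

as_region_set <- function(regions) {
  required <- c("chrom", "start", "end")
  if (!all(required %in% names(regions)))
    stop("regions need chrom/start/end columns")
  regions$start <- as.numeric(regions$start)
  regions$end <- as.numeric(regions$end)
  if (any(regions$start != round(regions$start)) ||
      any(regions$end != round(regions$end)))
    stop("non-integer region coordinates")
  if (any(regions$start < 0)) stop("negative region start")
  if (any(regions$start >= regions$end))
    stop("region start must be < end (0-based half-open)")
  if (is.null(regions$name) || anyNA(regions$name))
    regions$name <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                            regions$end)
  if (anyDuplicated(regions$name))
    stop("duplicate region names: ",
         paste(unique(regions$name[duplicated(regions$name)]), collapse = ", "))
  if (is.null(regions$score)) regions$score <- 0
  if (is.null(regions$strand)) regions$strand <- "."
  regions$strand[is.na(regions$strand)] <- "."
  if (!all(regions$strand %in% c("+", "-", ".")))
    stop("strand must be one of +, -, .")
  regions[c("chrom", "start", "end", "name", "score", "strand")]
}

## 0-based half-open data.frame -> 1-based closed GRanges
regions_to_granges <- function(regions) {
  regions <- as_region_set(regions)
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = ifelse(regions$strand == ".", "*", regions$strand),
    name = regions$name, score = regions$score
  )
}

granges_to_regions <- function(gr) {
  name <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  score <- if (!is.null(gr$score)) as.numeric(gr$score) else 0
  score[is.na(score)] <- 0
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  as_region_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = name, score = score, strand = strand,
    stringsAsFactors = FALSE
  ))
}

#' Read / write regions in BED format
#'
#' BED3 to BED6 lines are accepted (track and comment lines tolerated).
#' Coordinates are kept 0-based half-open. Missing names are auto-generated
#' as `chrom:start-end`; missing strand becomes `"."`. BED6 files round-trip
#' losslessly.
#'
#' @param path BED file path.
#' @return `read_regions_bed()`: a region data.frame with columns `chrom`,
#'   `start`, `end`, `name`, `score`, `strand`.
#' @export
read_regions_bed <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  granges_to_regions(gr)
}

#' @rdname read_regions_bed
#' @param regions a region data.frame (`chrom`, `start`, `end`, and
#'   optionally `name`, `score`, `strand`).
#' @export
write_regions_bed <- function(regions, path) {
  gr <- regions_to_granges(regions)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Derive promoter windows from gene bodies
#'
#' The TSS of a `+` (or unstranded) gene is its `start`; of a `-` gene its
#' `end`. The promoter is `[max(0, TSS - upstream), TSS + downstream)` on the
#' `+` strand and the strand-mirrored window `[max(0, TSS - downstream),
#' TSS + upstream)` on the `-` strand. The default 2 kb on either side is a
#' common window for promoter-mark quantification.
#'
#' @param genes region data.frame of gene bodies.
#' @param upstream,downstream non-negative widths in bp (not both 0).
#' @return Region data.frame of promoters; names inherit the gene names with
#'   a `_promoter` suffix.
#' @export
promoters_from_genes <- function(genes, upstream = 2000, downstream = 2000) {
  genes <- as_region_set(genes)
  if (nrow(genes) == 0L) stop("empty gene set")
  if (upstream < 0 || downstream < 0) stop("flanks must be >= 0")
  if (upstream == 0 && downstream == 0) stop("upstream and downstream both 0")
  minus <- genes$strand == "-"
  tss <- ifelse(minus, genes$end, genes$start)
  start <- ifelse(minus, tss - downstream, tss - upstream)
  end <- ifelse(minus, tss + upstream, tss + downstream)
  out <- data.frame(
    chrom = genes$chrom,
    start = pmax(0, start),
    end = end,
    name = paste0(genes$name, "_promoter"),
    score = genes$score,
    strand = genes$strand,
    stringsAsFactors = FALSE
  )
  as_region_set(out)
}

read_bedgraph_granges <- function(path) {
  bg <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop("malformed bedGraph file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  red <- GenomicRanges::reduce(bg)
  if (sum(BiocGenerics::width(red)) < sum(BiocGenerics::width(bg)))
    warning("overlapping bedGraph intervals; overlapping values are summed")
  bg
}

#' Aggregate bedGraph coverage over regions
#'
#' For each region, `sum` mode returns the base-pair-weighted sum of the
#' bedGraph values over the region (`sum(value * overlap_bp)`); `mean`
#' divides by the region length. Regions without any overlapping interval
#' get 0.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param regions region data.frame.
#' @param mode `"sum"` or `"mean"`.
#' @return Named numeric vector, one value per region.
#' @export
region_coverage_from_bedgraph <- function(path, regions,
                                          mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  regions <- as_region_set(regions)
  gr <- regions_to_granges(regions)
  bg <- read_bedgraph_granges(path)
  hits <- GenomicRanges::findOverlaps(gr, bg)
  ov <- BiocGenerics::width(IRanges::pintersect(
    gr[S4Vectors::queryHits(hits)], bg[S4Vectors::subjectHits(hits)]))
  val <- bg$score[S4Vectors::subjectHits(hits)] * ov
  out <- stats::setNames(numeric(nrow(regions)), regions$name)
  agg <- tapply(val, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  if (mode == "mean") out <- out / (regions$end - regions$start)
  out
}

#' Binning schemes for region signal
#'
#' `bin_scheme_tss()` centers fixed-width bins on the TSS (`2 * flank /
#' bin_width` bins); `bin_scheme_body()` scales gene bodies to a fixed number
#' of bins with fixed-width flanks on either side. Bins are always reported
#' 5' to 3': minus-strand regions are reversed.
#'
#' @param flank flank size in bp.
#' @param bin_width,flank_bin_width bin width in bp (must divide `flank`).
#' @param n_body_bins number of equal-width bins the region body is scaled
#'   to.
#' @return A list describing the scheme, for [bin_region_signal()].
#' @export
bin_scheme_tss <- function(flank = 2000, bin_width = 100) {
  if (bin_width <= 0 || flank <= 0) stop("flank and bin_width must be > 0")
  if (bin_width > flank) stop("bin_width larger than flank")
  if (flank %% bin_width != 0) stop("bin_width must divide flank")
  list(type = "tss", flank = flank, bin_width = bin_width,
       n_bins = as.integer(2 * flank / bin_width))
}

#' @rdname bin_scheme_tss
#' @export
bin_scheme_body <- function(flank = 2000, n_body_bins = 20,
                            flank_bin_width = 100) {
  if (n_body_bins < 1) stop("need at least one body bin")
  if (flank < 0) stop("flank must be >= 0")
  if (flank > 0) {
    if (flank_bin_width <= 0 || flank_bin_width > flank)
      stop("flank_bin_width must be in (0, flank]")
    if (flank %% flank_bin_width != 0)
      stop("flank_bin_width must divide flank")
  }
  nf <- if (flank > 0) as.integer(flank / flank_bin_width) else 0L
  list(type = "body", flank = flank, n_body_bins = as.integer(n_body_bins),
       flank_bin_width = flank_bin_width,
       n_bins = as.integer(2L * nf + n_body_bins))
}

## Per-base coverage for a 0-based half-open window, zero-padded outside the
## extent of the bedGraph.
window_values <- function(covlist, chrom, start0, end0) {
  n <- end0 - start0
  out <- numeric(n)
  if (!chrom %in% names(covlist)) return(out)
  rle <- covlist[[chrom]]
  len <- length(rle)
  lo <- max(start0, 0)
  hi <- min(end0, len)
  if (hi > lo)
    out[(lo - start0 + 1):(hi - start0)] <-
      as.numeric(S4Vectors::window(rle, start = lo + 1, end = hi))
  out
}

#' Bin bedGraph signal over regions
#'
#' Computes per-region, per-bin mean coverage under a TSS-centered or
#' scaled-body scheme (see [bin_scheme_tss()]). Minus-strand regions have
#' their bins reversed so that bin 1 is always the 5' end.
#'
#' @param path bedGraph file.
#' @param regions region data.frame.
#' @param scheme a [bin_scheme_tss()] or [bin_scheme_body()].
#' @return Numeric matrix, regions by bins, with the scheme attached as
#'   attribute `"scheme"`.
#' @export
bin_region_signal <- function(path, regions, scheme) {
  regions <- as_region_set(regions)
  bg <- read_bedgraph_granges(path)
  covlist <- GenomicRanges::coverage(bg, weight = bg$score)
  n_bins <- scheme$n_bins
  if (n_bins < 1) stop("scheme has zero bins")
  out <- matrix(0, nrow(regions), n_bins,
                dimnames = list(regions$name, NULL))
  for (i in seq_len(nrow(regions))) {
    minus <- regions$strand[i] == "-"
    if (scheme$type == "tss") {
      tss <- if (minus) regions$end[i] else regions$start[i]
      v <- window_values(covlist, regions$chrom[i], tss - scheme$flank,
                         tss + scheme$flank)
      if (minus) v <- rev(v)
      out[i, ] <- colMeans(matrix(v, nrow = scheme$bin_width))
    } else {
      v <- window_values(covlist, regions$chrom[i],
                         regions$start[i] - scheme$flank,
                         regions$end[i] + scheme$flank)
      if (minus) v <- rev(v)
      nf <- if (scheme$flank > 0)
        as.integer(scheme$flank / scheme$flank_bin_width) else 0L
      body_len <- regions$end[i] - regions$start[i]
      bins <- numeric(0)
      if (nf > 0)
        bins <- colMeans(matrix(v[seq_len(scheme$flank)],
                                nrow = scheme$flank_bin_width))
      body <- v[(scheme$flank + 1):(scheme$flank + body_len)]
      cuts <- round(seq(0, body_len, length.out = scheme$n_body_bins + 1))
      bins <- c(bins, vapply(seq_len(scheme$n_body_bins), function(b) {
        mean(body[(cuts[b] + 1):cuts[b + 1]])
      }, numeric(1)))
      if (nf > 0)
        bins <- c(bins, colMeans(matrix(
          v[(scheme$flank + body_len + 1):(2 * scheme$flank + body_len)],
          nrow = scheme$flank_bin_width)))
      out[i, ] <- bins
    }
  }
  attr(out, "scheme") <- scheme
  out
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member genes. Duplicate genes within a set are removed (first occurrence
#' kept); set order is preserved.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: a named list of character vectors, with set
#'   descriptions in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, desc, unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
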