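test_that("GTF reading converts coordinates and ranks exons by strand", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t501\t600\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    'chr1\tsrc\texon\t301\t400\t.\t-\t.\tgene_id "g2"; transcript_id "t2";'),
    gtf)
  ann <- read_gtf(gtf)
  t1 <- ann[ann$transcript_id == "t1", ]
  expect_equal(t1$start, c(100, 300))
  expect_equal(t1$end, c(200, 400))
  expect_equal(t1$rank, c(1L, 2L))
  # minus strand: rank 1 is the rightmost genomic block
  t2 <- ann[ann$transcript_id == "t2", ]
  expect_equal(t2$rank[t2$start == 500], 1L)
  expect_equal(t2$rank[t2$start == 300], 2L)
})

test_that("GTF errors name the offending line", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\tsrc\texon\tnot_a_number"), bad)
  expect_error(read_gtf(bad), "line 2")
  noid <- tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1";', noid)
  expect_error(read_gtf(noid), "transcript_id")
})

test_that("GTF round-trip is coordinate- and id-exact", {
  ann <- make_annotation(
    list(gene = "gA", tx = "tA1", strand = "+", exons = ex(10, 50, 80, 120)),
    list(gene = "gA", tx = "tA2", strand = "+", exons = ex(10, 50, 200, 260)),
    list(gene = "gB", tx = "tB1", strand = "-", exons = ex(400, 450, 500, 570)))
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  back <- read_gtf(path)
  cols <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end",
            "rank")
  expect_equal(back[, cols], ann[, cols])
})

test_that("BED reading is verbatim 0-based and order-preserving", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tp1\t37\t+", "chr1\t5\t8\tp2\t2\t-"), bed)
  x <- read_bed(bed, scored = TRUE)
  expect_equal(x$start, c(10, 5))
  expect_equal(x$end, c(20, 8))
  expect_equal(x$score, c(37, 2))
  expect_equal(x$strand, c("+", "-"))
  bed3 <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed3)
  expect_null(read_bed(bed3, scored = FALSE)$score)
  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t20\t10", bad)
  expect_error(read_bed(bad), "start >= end")
})

test_that("a generated 1000-line BED survives a round trip intact", {
  withr::with_seed(7, {
    n <- 1000
    s <- sample.int(1e6, n, replace = TRUE)
    x <- genome_intervals(chrom = sample(c("chr1", "chr2"), n, TRUE),
                          start = s, end = s + sample.int(500, n, replace = TRUE),
                          strand = sample(c("+", "-"), n, TRUE))
    x$name <- sprintf("iv%04d", seq_len(n))
    x$score <- sample.int(1000, n, replace = TRUE)
  })
  path <- tempfile(fileext = ".bed")
  write_bed(x, path)
  back <- read_bed(path, scored = TRUE)
  expect_equal(nrow(back), n)
  expect_equal(back$start, x$start)
  expect_equal(back$name, x$name)
  expect_equal(back$score, as.numeric(x$score))
})

test_that("intersect matches a brute-force all-pairs scan and is symmetric", {
  withr::with_seed(11, {
    mk <- function(n) {
      s <- sample.int(5000, n, replace = TRUE)
      genome_intervals(chrom = sample(c("chr1", "chr2"), n, TRUE),
                       start = s, end = s + sample.int(200, n, replace = TRUE),
                       strand = sample(c("+", "-", "."), n, TRUE))
    }
    a <- mk(500)
    b <- mk(500)
  })
  got <- intersect_intervals(a, b)
  want <- brute_overlaps(a, b)
  o <- function(d) d[order(d$a_idx, d$b_idx), ]
  expect_equal(o(got), o(want), ignore_attr = TRUE)
  # symmetry
  rev <- intersect_intervals(b, a)
  expect_equal(o(data.frame(a_idx = rev$b_idx, b_idx = rev$a_idx)), o(want),
               ignore_attr = TRUE)
  # stranded variant
  got_s <- intersect_intervals(a, b, stranded = TRUE)
  want_s <- brute_overlaps(a, b, stranded = TRUE)
  expect_equal(o(got_s), o(want_s), ignore_attr = TRUE)
  # -v mode complements the matched set
  no <- intersect_intervals(a, b, mode = "no_overlap")
  expect_equal(nrow(no), 500 - length(unique(want$a_idx)))
})

test_that("intersect boundary semantics are half-open", {
  a <- genome_intervals("chr1", 10, 20)
  expect_equal(nrow(intersect_intervals(a, genome_intervals("chr1", 19, 30))), 1)
  expect_equal(nrow(intersect_intervals(a, genome_intervals("chr1", 20, 30))), 0)
})

test_that("merge_near uses a strict gap rule and reaches the pairwise fixpoint", {
  x <- genome_intervals(c("chr1", "chr1"), c(0, 19), c(10, 30))
  m <- merge_near(x, 10)
  expect_equal(m[, c("start", "end")], data.frame(start = 0, end = 30))
  y <- genome_intervals(c("chr1", "chr1"), c(0, 20), c(10, 30))
  expect_equal(nrow(merge_near(y, 10)), 2)      # gap exactly 10: kept apart
  expect_equal(nrow(merge_near(y, 10, closed = TRUE)), 1)  # bedtools -d mode

  # 200 random intervals: result equals iterated pairwise merging
  withr::with_seed(13, {
    s <- sample.int(3000, 200, replace = TRUE)
    z <- genome_intervals("chr1", s, s + sample.int(60, 200, replace = TRUE))
  })
  got <- merge_near(z, 25)
  ref <- z[order(z$start), ]
  repeat {
    done <- TRUE
    i <- 1
    while (i < nrow(ref)) {
      if (ref$start[i + 1] - ref$end[i] < 25) {
        ref$end[i] <- max(ref$end[i], ref$end[i + 1])
        ref <- ref[-(i + 1), ]
        done <- FALSE
      } else i <- i + 1
    }
    if (done) break
  }
  expect_equal(got$start, ref$start)
  expect_equal(got$end, ref$end)
  # output gaps all >= max_gap
  expect_true(all(diff(got$start) - (got$end[-nrow(got)] - got$start[-nrow(got)]) >= 25))
})

test_that("BH adjustment matches an independent step-up and keeps missings", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  withr::with_seed(17, p <- runif(1000))
  expect_equal(bh_adjust(p), bh_reference(p))
  # missing values are excluded from m and preserved in place
  p2 <- c(0.01, NA, 0.04)
  got <- bh_adjust(p2)
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], bh_reference(c(0.01, 0.04)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotonicity and dominance
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(diff(bh_adjust(sort(p))) >= 0))
})
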