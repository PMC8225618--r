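toy_sig <- function(donor_end = 100L, acceptor_start = 201L,
                    chrom = "chrT") {
  data.frame(transcript_id = "TX", donor_exon = "A", acceptor_exon = "B",
             donor_end = donor_end, acceptor_start = acceptor_start,
             chrom = chrom, strand = "+", stringsAsFactors = FALSE)
}

test_that("parse_sam decodes mapped records and applies flag filters", {
  lines <- c(sam_header("chrT"),
             sam_line("r1", 0L, "chrT", 91L, "10M100N10M"),
             sam_line("r2", 4L, "*", 0L, "*"),          # unmapped
             sam_line("r3", 256L, "chrT", 50L, "20M"),  # secondary
             sam_line("r4", 2048L, "chrT", 60L, "5M"))  # supplementary
  reads <- parse_sam(lines)
  expect_equal(reads$read_id, "r1")
  expect_equal(reads$pos, 91L)
  expect_equal(reads$cigar, "10M100N10M")
  reads2 <- parse_sam(lines, keep_secondary = TRUE)
  expect_setequal(reads2$read_id, c("r1", "r3", "r4"))
  expect_error(parse_sam(c(sam_header("chrT"),
                           sam_line("r5", 0L, "chrT", 10L, "10M$"))),
               "CIGAR")
  expect_equal(nrow(parse_sam(sam_header("chrT"))), 0)
})

test_that("read_spans_junction requires the exact skip plus anchors", {
  sig <- toy_sig()
  rd <- function(pos, cigar) list(chrom = "chrT", pos = pos, cigar = cigar)
  # 10-base anchors around the exact 101-200 skip
  expect_true(read_spans_junction(rd(91L, "10M100N10M"), sig, 6L))
  # unspliced read
  expect_false(read_spans_junction(rd(50L, "20M"), sig, 6L))
  # left anchor of 3 < 6
  expect_false(read_spans_junction(rd(98L, "3M100N17M"), sig, 6L))
  # off-by-one skip
  expect_false(read_spans_junction(rd(92L, "10M100N10M"), sig, 6L))
  # ...accepted under a 1-base tolerance
  expect_true(read_spans_junction(rd(92L, "10M100N10M"), sig, 6L,
                                  tolerance = 1L))
  # insertion does not break the anchor on the reference
  expect_true(read_spans_junction(rd(95L, "3M2I3M100N10M"), sig, 6L))
  # deletion adjacent to the splice does
  expect_false(read_spans_junction(rd(89L, "10M2D100N10M"), sig, 6L))
  # wrong chromosome
  sig2 <- toy_sig(chrom = "chrX")
  expect_false(read_spans_junction(rd(91L, "10M100N10M"), sig2, 6L))
})

test_that("count_junction_reads assigns reads and calls positivity", {
  m <- build_toy_ar_model()
  fl <- m$signatures[m$signatures$transcript_id == "AR-FL", ]
  lines <- c(sam_header(),
             vapply(1:5, function(i) {
               sam_line(paste0("s", i), 0L, "chrT_AR",
                        fl$donor_end - 9L, "10M100N10M")
             }, character(1)),
             vapply(1:3, function(i) {
               sam_line(paste0("b", i), 0L, "chrT_AR", 10L * i, "30M")
             }, character(1)))
  counts <- count_junction_reads(parse_sam(lines), m)
  fl_row <- counts[counts$transcript_id == "AR-FL", ]
  expect_equal(fl_row$spanning_reads, 5L)
  expect_true(fl_row$positive)
  expect_equal(unique(counts$total_reads_screened), 8L)
  expect_false(any(counts$positive[counts$transcript_id != "AR-FL"]))

  # empty read set: all zero, all negative
  empty <- count_junction_reads(parse_sam(sam_header()), m)
  expect_equal(empty$spanning_reads, c(0L, 0L, 0L))
  expect_false(any(empty$positive))

  # only AR-V7 junction reads
  v7 <- m$signatures[m$signatures$transcript_id == "AR-V7", ]
  k <- v7$acceptor_start - v7$donor_end - 1L
  lines_v7 <- c(sam_header(),
                sam_line("v", 0L, "chrT_AR", v7$donor_end - 7L,
                         sprintf("8M%dN8M", k)))
  c2 <- count_junction_reads(parse_sam(lines_v7), m)
  expect_true(c2$positive[c2$transcript_id == "AR-V7"])
  expect_false(any(c2$positive[c2$transcript_id != "AR-V7"]))
})

test_that("counting refuses to run on a colliding model", {
  m <- build_toy_ar_model()
  v9 <- transform(m$signatures[m$signatures$transcript_id == "AR-V7", ],
                  transcript_id = "AR-V9")
  m$signatures <- rbind(m$signatures, v9)
  expect_error(count_junction_reads(parse_sam(sam_header()), m),
               "collision")
})

test_that("counter matches the base-projection oracle on random reads", {
  m <- build_toy_ar_model()
  set.seed(42)
  lines <- sam_header()
  for (i in 1:200) {
    kind <- sample(c("junction", "near", "plain"), 1)
    if (kind == "junction") {
      s <- m$signatures[sample.int(3, 1), ]
      a <- sample(1:12, 1); b <- sample(1:12, 1)
      k <- s$acceptor_start - s$donor_end - 1L
      pos <- s$donor_end - a + 1L
      cigar <- sprintf("%dM%dN%dM", a, k, b)
    } else if (kind == "near") {
      s <- m$signatures[sample.int(3, 1), ]
      a <- sample(5:12, 1); b <- sample(5:12, 1)
      k <- s$acceptor_start - s$donor_end - 1L + sample(-2:2, 1)
      pos <- s$donor_end - a + 1L + sample(-2:2, 1)
      cigar <- sprintf("%dM%dN%dM", a, max(k, 1L), b)
    } else {
      pos <- sample(1:1800, 1)
      cigar <- sprintf("%dM", sample(20:80, 1))
    }
    lines <- c(lines, sam_line(sprintf("x%03d", i), 0L, "chrT_AR",
                               pos, cigar))
  }
  reads <- parse_sam(lines)
  for (mo in c(3L, 6L, 10L)) {
    got <- count_junction_reads(reads, m, min_overhang = mo)
    want <- oracle_count(reads, m, mo)
    expect_equal(setNames(got$spanning_reads, got$transcript_id), want,
                 info = paste("min_overhang", mo))
  }
  # monotonicity in min_overhang and conservation
  totals <- vapply(c(1L, 3L, 6L, 10L, 15L), function(mo) {
    sum(count_junction_reads(reads, m, min_overhang = mo)$spanning_reads)
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
  n_spliced <- sum(grepl("N", reads$cigar))
  expect_true(all(totals <= n_spliced))
})
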