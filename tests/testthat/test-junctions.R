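make_jx <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (is.null(df$min_overhang)) df$min_overhang <- 25L
  if (is.null(df$intron_coverage)) df$intron_coverage <- 0L
  if (is.null(df$sample_id)) df$sample_id <- "s1"
  df
}

simple_models <- function(gene_start = 0L, gene_end = 10000L,
                          strand = "+",
                          exons = list(c(0L, 1000L), c(2000L, 3000L),
                                       c(4000L, 5000L))) {
  list(genes = data.frame(gene_id = "g1", chrom = "chr1",
                          start = gene_start, end = gene_end,
                          strand = strand, stringsAsFactors = FALSE),
       exons = do.call(rbind, lapply(seq_along(exons), function(i)
         data.frame(gene_id = "g1", exon_rank = i, chrom = "chr1",
                    start = exons[[i]][1], end = exons[[i]][2],
                    strand = strand, stringsAsFactors = FALSE))))
}

test_that("load_junctions applies the overhang and intron-size filters", {
  jx <- make_jx(
    list(chrom = "chr1", start = 100L, end = 300L, strand = "+",
         reads = 5L, min_overhang = 12L),     # overhang below 13: dropped
    list(chrom = "chr1", start = 100L, end = 140L, strand = "+",
         reads = 5L, min_overhang = 20L),     # intron length 40: dropped
    list(chrom = "chr1", start = 100L, end = 141L, strand = "+",
         reads = 5L, min_overhang = 13L),     # length 41, overhang 13: kept
    list(chrom = "chr1", start = 100L, end = 50101L, strand = "+",
         reads = 5L, min_overhang = 20L),     # length 50001: dropped
    list(chrom = "chr1", start = 200L, end = 50200L, strand = "+",
         reads = 5L, min_overhang = 20L))     # length 50000: kept
  out <- load_junctions(jx)
  expect_identical(nrow(out), 2L)
  expect_setequal(out$end - out$start, c(41L, 50000L))
})

test_that("duplicate junctions merge by summing reads", {
  jx <- make_jx(
    list(chrom = "chr1", start = 100L, end = 300L, strand = "+",
         reads = 5L),
    list(chrom = "chr1", start = 100L, end = 300L, strand = "+",
         reads = 7L))
  out <- load_junctions(jx)
  expect_identical(nrow(out), 1L)
  expect_identical(out$reads, 12L)
})

test_that("filtering is idempotent and malformed input errors", {
  jx <- make_jx(
    list(chrom = "chr1", start = 100L, end = 300L, strand = "+",
         reads = 5L, min_overhang = 30L),
    list(chrom = "chr1", start = 500L, end = 900L, strand = "-",
         reads = 3L, min_overhang = 12L))
  once <- load_junctions(jx)
  twice <- load_junctions(once)
  expect_equal(twice, once)
  bad <- jx; bad$reads[1] <- -2L
  expect_error(load_junctions(bad), "negative")
  bad2 <- jx; bad2$start[2] <- "oops"
  expect_error(load_junctions(bad2), "line 3")
})

test_that("shared donors / acceptors classify as AltA / AltD (strand-aware)", {
  gm <- simple_models(exons = list(c(0L, 1000L), c(2000L, 3000L)))
  # plus strand: same start (donor shared) = AltA
  jx <- make_jx(
    list(chrom = "chr1", start = 1000L, end = 2000L, strand = "+",
         reads = 30L),
    list(chrom = "chr1", start = 1000L, end = 2100L, strand = "+",
         reads = 10L))
  ev <- classify_as_events(load_junctions(jx), gm, "s1")
  expect_identical(ev$type, "AltA")
  # shorter intron is the inclusion isoform
  expect_identical(ev$inclusion_reads, 30L)
  expect_equal(ev$psi, 0.75)
  # plus strand: same end (acceptor shared) = AltD
  jx2 <- make_jx(
    list(chrom = "chr1", start = 1000L, end = 2000L, strand = "+",
         reads = 30L),
    list(chrom = "chr1", start = 950L, end = 2000L, strand = "+",
         reads = 10L))
  gm2 <- simple_models(exons = list(c(0L, 1000L), c(2000L, 3000L)))
  ev2 <- classify_as_events(load_junctions(jx2), gm2, "s1")
  expect_identical(ev2$type, "AltD")
  # minus strand: shared start is the acceptor side, so AltD
  gm3 <- simple_models(strand = "-",
                       exons = list(c(0L, 1000L), c(2000L, 3000L)))
  jx3 <- make_jx(
    list(chrom = "chr1", start = 1000L, end = 2000L, strand = "-",
         reads = 30L),
    list(chrom = "chr1", start = 1000L, end = 2100L, strand = "-",
         reads = 10L))
  ev3 <- classify_as_events(load_junctions(jx3), gm3, "s1")
  expect_identical(ev3$type, "AltD")
})

test_that("IR support counts junction reads plus intronic coverage", {
  gm <- simple_models(exons = list(c(0L, 1000L), c(2000L, 3000L)))
  jx <- make_jx(
    list(chrom = "chr1", start = 1000L, end = 2000L, strand = "+",
         reads = 20L, intron_coverage = 15L))
  ev <- classify_as_events(load_junctions(jx), gm, "s1")
  expect_identical(ev$type, "IR")
  expect_identical(ev$total_support, 35L)
  expect_equal(ev$psi, 15 / 35)
})

test_that("ES requires all three junctions and an annotated middle exon", {
  gm <- simple_models()
  jx_full <- make_jx(
    list(chrom = "chr1", start = 1000L, end = 2000L, strand = "+",
         reads = 12L),
    list(chrom = "chr1", start = 3000L, end = 4000L, strand = "+",
         reads = 14L),
    list(chrom = "chr1", start = 1000L, end = 4000L, strand = "+",
         reads = 6L))
  ev <- classify_as_events(load_junctions(jx_full), gm, "s1")
  es <- ev[ev$type == "ES", ]
  expect_identical(nrow(es), 1L)
  expect_identical(es$inclusion_reads, 26L)
  expect_identical(es$exclusion_reads, 6L)
  # no spurious AltA/AltD from the ES triple
  expect_identical(nrow(ev), 1L)
  # partial evidence (missing one inclusion junction) yields no event
  ev2 <- classify_as_events(load_junctions(jx_full[-2, ]), gm, "s1")
  expect_identical(nrow(ev2[ev2$type == "ES", ]), 0L)
})

test_that("compute_psi follows the formula and the 10-read rule", {
  expect_equal(compute_psi(30, 10), 0.75)
  expect_true(is.na(compute_psi(6, 3)))
  expect_equal(compute_psi(0, 20), 0)
  expect_error(compute_psi(-1, 5), "non-negative")
  # inclusion and exclusion PSI are complementary
  for (i in c(10, 25, 40)) {
    expect_equal(compute_psi(i, 50 - i), 1 - compute_psi(50 - i, i))
  }
})

test_that("classified event types equal planted types on the cohort", {
  co <- tiny_cohort()
  for (sp in names(co$species)) {
    spd <- co$species[[sp]]
    ev <- classify_species(spd)
    tr <- co$truth$events[co$truth$events$species == sp, ]
    for (k in seq_len(nrow(tr))) {
      r <- tr[k, ]
      # the authentic junction's events at these coordinates must be of
      # exactly the planted type
      at <- ev[(ev$excl_start == r$start & ev$excl_end == r$end) |
                 (ev$excl_start == r$alt_start &
                    ev$excl_end == r$alt_end), ]
      expect_true(all(at$type == r$type), info = r$event_id)
      expect_gt(nrow(at), 0)
    }
  }
})
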