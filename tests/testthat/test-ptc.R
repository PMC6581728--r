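test_that("longest_orf translates, breaks ties 5'-most and honours N", {
  o <- longest_orf("ATGAAATAG")
  expect_identical(o$length, 9L)
  expect_identical(o$protein, "MK")
  expect_null(longest_orf("CCCCCCGGGTTT"))
  # two equal-length ORFs: the 5'-most wins
  two <- paste0("ATGAAATAG", "T", "ATGCCCTAG")
  o2 <- longest_orf(two)
  expect_identical(o2$start, 1L)
  # N inside the candidate ORF aborts it
  expect_null(longest_orf("ATGANATAG"))
  # ORF without stop runs to the transcript end, codon-truncated
  o3 <- longest_orf("ATGAAAAAAA")
  expect_false(o3$has_stop)
  expect_identical(o3$length %% 3L, 0L)
})

# transcript with a stop placed `gap` nt upstream of the final junction
tx_with_gap <- function(gap) {
  # layout: 20nt UTR, ORF, then the final junction `gap` nt after the
  # stop, then a 60nt final exon
  orf <- paste0("ATG", strrep("AAA", 30), "TAA")
  pre <- paste0(strrep("C", 20), orf)
  mature <- paste0(pre, strrep("C", max(gap, 0)), strrep("G", 60))
  junctions <- c(20L, nchar(pre) + gap)
  list(transcript_id = "t", mature = mature,
       junctions = junctions[junctions > 0], blocks = NULL, strand = "+")
}

test_that("the 50-nt rule boundary behaves exactly", {
  expect_true(annotate_ptc(tx_with_gap(60))$has_ptc)
  expect_true(annotate_ptc(tx_with_gap(50))$has_ptc)
  expect_false(annotate_ptc(tx_with_gap(49))$has_ptc)
  expect_equal(annotate_ptc(tx_with_gap(50))$distance_to_final_junction,
               50)
  # stop within the final exon (downstream of all junctions): no PTC
  tx <- tx_with_gap(60)
  tx$junctions <- c(10L)   # all junctions upstream of the stop
  expect_false(annotate_ptc(tx)$has_ptc)
  # single-exon transcript: no PTC by definition
  tx$junctions <- integer(0)
  expect_false(annotate_ptc(tx)$has_ptc)
})

test_that("annotate_ptc is invariant to genomic strand", {
  co <- tiny_cohort()
  spd <- co$species$sp1
  tx <- spd$transcripts
  tx <- tx[!is.na(tx$event_id), ][1:4, ]
  for (k in seq_len(nrow(tx))) {
    blocks <- splicevol:::.decode_blocks(tx$blocks[k])
    mod <- build_transcript_model(spd$genome, "chr1", blocks,
                                  tx$strand[k], tx$transcript_id[k])
    # re-embed the same mature sequence on the opposite strand of a
    # synthetic chromosome: annotation must not change
    flip <- list(chr1 = splicevol:::revcomp(spd$genome[["chr1"]]))
    L <- nchar(spd$genome[["chr1"]])
    blocks_f <- rev(lapply(blocks, function(b) c(L - b[2], L - b[1])))
    mod_f <- build_transcript_model(
      flip, "chr1", blocks_f,
      if (tx$strand[k] == "+") "-" else "+", tx$transcript_id[k])
    expect_identical(mod_f$mature, mod$mature)
    expect_identical(annotate_ptc(mod_f)$has_ptc,
                     annotate_ptc(mod)$has_ptc)
  }
})

test_that("classify_event_ptc applies the three criteria", {
  mk_tx <- function(mature, junctions, blocks) {
    list(transcript_id = "t", mature = mature, junctions = junctions,
         blocks = blocks, strand = "+")
  }
  b_maj <- list(c(0L, 100L), c(200L, 300L), c(400L, 500L))
  b_min <- list(c(0L, 100L), c(200L, 320L), c(400L, 500L))
  ev <- list(excl_start = 200L, excl_end = 400L,
             incl_start = 200L, incl_end = 400L)
  ptc_y <- list(has_ptc = TRUE); ptc_n <- list(has_ptc = FALSE)
  t1 <- mk_tx("ATG", 1L, b_maj); t2 <- mk_tx("ATG", 1L, b_min)
  # three transcripts: unassigned
  expect_identical(classify_event_ptc(ev, list(t1, t2, t1)), "unassigned")
  # both PTC+: excluded
  expect_identical(classify_event_ptc(ev, list(t1, t2),
                                      list(ptc_y, ptc_y)), "unassigned")
  # one PTC+, one PTC-: AS_plus_PTC
  expect_identical(classify_event_ptc(ev, list(t1, t2),
                                      list(ptc_y, ptc_n)), "AS_plus_PTC")
  expect_identical(classify_event_ptc(ev, list(t1, t2),
                                      list(ptc_n, ptc_n)), "AS_minus_PTC")
  # structural difference outside the AS region: unassigned
  b_far <- list(c(0L, 120L), c(200L, 300L), c(400L, 500L))
  t3 <- mk_tx("ATG", 1L, b_far)
  expect_identical(classify_event_ptc(ev, list(t1, t3),
                                      list(ptc_y, ptc_n)), "unassigned")
})

test_that("planted PTC isoforms are flagged perfectly on the cohort", {
  co <- tiny_cohort()
  n_checked <- 0L
  for (sp in names(co$species)) {
    spd <- co$species[[sp]]
    cls <- event_ptc_classes(spd)
    tr <- co$truth$events[co$truth$events$species == sp, ]
    m <- merge(cls, tr[, c("event_id", "ptc_planted")], by = "event_id")
    expect_identical(m$minor_has_ptc, m$ptc_planted)
    expect_true(all(!m$major_has_ptc))
    expect_identical(m$class[m$ptc_planted], rep("AS_plus_PTC",
                                                 sum(m$ptc_planted)))
    expect_identical(m$class[!m$ptc_planted],
                     rep("AS_minus_PTC", sum(!m$ptc_planted)))
    n_checked <- n_checked + nrow(m)
  }
  expect_gt(n_checked, 10L)
})

test_that("PTC x conservation contingency analysis", {
  tab <- matrix(c(8L, 1L, 20L, 80L), 2, byrow = TRUE)
  res <- compare_ptc_conservation(tab)
  expect_equal(res$odds_ratio, 32)
  expect_lte(res$p_value, 1)
  # identical conservation rates: p ~ 1
  null <- compare_ptc_conservation(matrix(c(10L, 40L, 10L, 40L), 2,
                                          byrow = TRUE))
  expect_gt(null$p_value, 0.9)
  expect_error(compare_ptc_conservation(matrix(0L, 2, 2)), "all-zero")
  # planted excess conservation of AS+PTC reaches significance
  set.seed(8)
  n <- 120
  ptc <- rep(c("AS_plus_PTC", "AS_minus_PTC"), each = n / 2)
  cons <- c(runif(n / 2) < 0.6, runif(n / 2) < 0.15)
  res2 <- compare_ptc_conservation(ptc, cons)
  expect_lt(res2$p_value, 0.05)
  expect_gt(res2$odds_ratio, 1)
})
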