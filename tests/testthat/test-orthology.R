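# protein-like random sequence helper
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

test_that("identical proteomes self-pair; ties and non-reciprocity drop", {
  set.seed(4)
  prots <- setNames(vapply(1:6, function(i) random_protein(120), ""),
                    paste0("g", 1:6))
  orth <- find_orthologs(prots, prots)
  expect_identical(nrow(orth), 6L)
  expect_identical(orth$gene_a, orth$gene_b)
  # a duplicated target creates an exact best-hit tie: the query drops
  dup <- c(prots, g1copy = unname(prots["g1"]))
  orth2 <- find_orthologs(prots, dup)
  expect_false("g1" %in% orth2$gene_a)
  expect_true(all(c("g2", "g3") %in% orth2$gene_a))
  expect_warning(find_orthologs(character(0), prots), "empty")
})

test_that("EEJ sequences are 100+100 bp, truncated at exon boundaries", {
  co <- tiny_cohort()
  spd <- co$species$sp1
  jx <- unique(spd$junctions[, c("chrom", "start", "end", "strand")])
  jx$gene_id <- splicevol:::.assign_genes(jx, spd$genes)
  jx <- jx[!is.na(jx$gene_id), ]
  r <- jx[1, ]
  gm <- list(exons = spd$exons[spd$exons$gene_id == r$gene_id, ])
  eej <- extract_eej_sequence(spd$genome, gm, r)
  ex <- gm$exons
  up_len <- min(100L, max(ex$end[ex$end == r$start] -
                            ex$start[ex$end == r$start]))
  expect_identical(eej$len_up + eej$len_down, nchar(eej$seq))
  expect_lte(eej$len_up, 100L); expect_lte(eej$len_down, 100L)
  # junction with no annotated flanking exon errors
  bad <- r; bad$start <- bad$start + 1L
  expect_error(extract_eej_sequence(spd$genome, gm, bad), "flanking")
})

test_that("minus-strand EEJ sequence is the reverse complement extract", {
  genome <- list(chr1 = paste(rep("ACGT", 200), collapse = ""))
  exons <- data.frame(gene_id = "g", exon_rank = 1:2, chrom = "chr1",
                      start = c(0L, 500L), end = c(200L, 700L),
                      strand = "-", stringsAsFactors = FALSE)
  j <- list(chrom = "chr1", start = 200L, end = 500L, strand = "-")
  eej_minus <- extract_eej_sequence(genome, list(exons = exons), j)
  j_plus <- modifyList(j, list(strand = "+"))
  exons$strand <- "+"
  eej_plus <- extract_eej_sequence(genome, list(exons = exons), j_plus)
  expect_identical(eej_minus$seq,
                   splicevol:::revcomp(eej_plus$seq))
})

test_that("match_eejs accepts identity and rejects the filter boundaries", {
  set.seed(11)
  # protein-coding-like flanks so translated alignment is clean
  coding <- function(naa) {
    paste(vapply(seq_len(naa), function(i)
      sample(setdiff(names(Biostrings::GENETIC_CODE)
                     [Biostrings::GENETIC_CODE != "*"], NULL), 1L), ""),
      collapse = "")
  }
  up <- coding(33); dn <- coding(33)  # ~100bp each flank
  eej <- function(id, seq, len_up, gene = "gA") {
    data.frame(junction_id = id, gene_id = gene, chrom = "chr1",
               start = 0L, end = 1L, strand = "+", seq = seq,
               len_up = len_up, len_down = nchar(seq) - len_up,
               stringsAsFactors = FALSE)
  }
  orth <- data.frame(gene_a = "gA", gene_b = "gA",
                     stringsAsFactors = FALSE)
  a <- eej("jA", paste0(up, dn), nchar(up))
  # identical sequences pass every filter
  m <- match_eejs(a, eej("jB", paste0(up, dn), nchar(up)), orth)
  expect_identical(nrow(m), 1L)
  expect_gte(m$aligned_aa_up, 3L)
  expect_gte(m$aligned_aa_down, 3L)
  expect_gte(m$coverage_bp, 60L)
  # downstream flank of 6 nt: at most 2 aa can align there, so the
  # 3-aa-per-flank filter rejects even a perfect alignment
  dn6 <- substr(dn, 1, 6)
  a6 <- eej("jA", paste0(up, dn6), nchar(up))
  m2 <- match_eejs(a6, eej("jB", paste0(up, dn6), nchar(up)), orth)
  expect_identical(nrow(m2), 0L)
  # only ~45 bp of alignable sequence: coverage filter rejects
  up_s <- coding(8); dn_s <- coding(7)       # 24 + 21 = 45 nt shared
  a_s <- eej("jA", paste0(up_s, dn_s), nchar(up_s))
  b_s <- eej("jB", paste0(up_s, dn_s), nchar(up_s))
  m3 <- match_eejs(a_s, b_s, orth)
  expect_identical(nrow(m3), 0L)
})

test_that("match_eejs is reciprocal on the pair cohort", {
  pc <- pair_conservation()
  ab <- pc$matches
  ba <- match_eejs(pc$eej_b, pc$eej_a, data.frame(
    gene_a = pc$orth$gene_b, gene_b = pc$orth$gene_a,
    stringsAsFactors = FALSE))
  key_ab <- sort(paste(ab$junction_a, ab$junction_b))
  key_ba <- sort(paste(ba$junction_b, ba$junction_a))
  expect_identical(key_ab, key_ba)
})

test_that("conservation labels follow the type rules", {
  lab_of <- function(ta, tb) {
    ev <- function(type, chrom = "chr1", s = 10L, e = 200L) {
      if (is.na(type)) return(splicevol:::.empty_events())
      data.frame(event_id = "e", gene_id = "g", type = type,
                 chrom = chrom, strand = "+",
                 incl_start = s, incl_end = e,
                 incl2_start = NA_integer_, incl2_end = NA_integer_,
                 excl_start = s, excl_end = e,
                 inclusion_reads = 20L, exclusion_reads = 10L,
                 total_support = 30L, psi = 2 / 3, sample_id = "s1",
                 stringsAsFactors = FALSE)
    }
    matches <- data.frame(junction_a = "chr1:10-200:+",
                          junction_b = "chr1:10-200:+",
                          stringsAsFactors = FALSE)
    call_conservation(matches, ev(ta), ev(tb))$state
  }
  expect_identical(lab_of("AltA", "AltA"), "conserved")
  expect_identical(lab_of("AltA", NA), "lost")
  expect_identical(lab_of(NA, "AltA"), "gained")
  expect_identical(lab_of("AltA", "IR"), "type_switch(AltA->IR)")
  expect_identical(lab_of(NA, NA), "none")
})

test_that("transition spectrum counts match construction and marginals", {
  states <- data.frame(
    as_type_a = c("AltA", "AltA", "none", "IR", "none"),
    as_type_b = c("AltA", "none", "AltD", "IR", "none"),
    stringsAsFactors = FALSE)
  ts <- transition_spectrum(states)
  expect_identical(sum(ts), 5L)
  expect_identical(ts["AltA", "AltA"], 1L)
  expect_identical(ts["AltA", "none"], 1L)
  expect_identical(ts["none", "AltD"], 1L)
  expect_identical(ts["IR", "IR"], 1L)
  expect_identical(ts["none", "none"], 1L)
  # marginals equal independent recounts per species
  expect_equal(rowSums(ts)[c("AltA", "IR", "none")],
               c(AltA = 2L, IR = 1L, none = 2L),
               ignore_attr = FALSE)
  expect_equal(unname(colSums(ts)["AltA"]),
               sum(states$as_type_b == "AltA"))
})

test_that("planted conservation labels are recovered on the pair cohort", {
  pc <- pair_conservation()
  calls <- event_conservation_calls(pc$cohort, pc$labels)
  acc <- mean(calls$got == calls$want)
  expect_gte(acc, 0.95)
  # transition-matrix grand total equals the labeled pair count
  ts <- transition_spectrum(pc$labels)
  expect_identical(sum(ts), nrow(pc$labels))
})
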