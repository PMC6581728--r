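test_that("find_tract matches specific boundary cases", {
  # pyrimidine-rich tail just before the AG
  hit <- find_tract(paste0("GT", strrep("A", 30), "TTTTCTTTT", "AG"),
                    "polypyrimidine")
  expect_false(is.null(hit))
  expect_gte(hit$length, 9L)
  expect_gt(hit$composition, 0.85)
  # a fully pyrimidine window is returned whole at composition 1
  pure <- find_tract(paste0("GT", strrep("G", 10), strrep("TC", 25), "AG"),
                     "polypyrimidine")
  expect_identical(pure$length, 50L)
  expect_equal(pure$composition, 1.0)
  # longest pyrimidine run of 4: below the length floor
  expect_null(find_tract(paste0("GT", strrep("GA", 20), "TTTT",
                                "GAGAGAGA", "AG"), "polypyrimidine"))
  # qualifying run ending 15 nt before the intron end: fails for
  # polypyrimidine, allowed for UA-free equivalents
  seq15 <- paste0("GT", strrep("G", 20), strrep("T", 8),
                  strrep("G", 13), "AG")
  expect_null(find_tract(seq15, "polypyrimidine"))
  ua15 <- paste0("GT", strrep("G", 20), strrep("AT", 4),
                 strrep("G", 13), "AG")
  expect_false(is.null(find_tract(ua15, "UA")))
})

test_that("find_tract equals the brute-force oracle on random windows", {
  set.seed(42)
  for (i in 1:200) {
    iseq <- paste0("GT", random_dna_str(sample(30:70, 1)), "AG")
    for (kind in c("polypyrimidine", "UA")) {
      got <- find_tract(iseq, kind)
      want <- oracle_tract(iseq, kind)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_identical(got[c("start", "end", "length")],
                         want[c("start", "end", "length")])
      }
    }
  }
})

test_that("find_branch_site follows the three-step rule", {
  # single perfect consensus
  b <- find_branch_site(paste0("GT", strrep("G", 40), "TACTAAC",
                               strrep("G", 25), "TTTTCAG"))
  expect_identical(b$heptamer, "TACTAAC")
  expect_identical(b$mismatches, 0L)
  # a worse hit downstream of a better one discards the intron
  b2 <- find_branch_site(paste0("GT", strrep("G", 30), "TACTAAC",
                                strrep("G", 10), "GGCTAAA",
                                strrep("G", 20), "AG"))
  expect_null(b2)
  # no heptamer at all
  expect_null(find_branch_site(paste0("GT", strrep("G", 60), "AG")))
})

test_that("find_branch_site equals the brute-force oracle", {
  set.seed(43)
  for (i in 1:200) {
    iseq <- paste0("GT", random_dna_str(sample(40:120, 1)), "AG")
    got <- find_branch_site(iseq)
    want <- oracle_branch(iseq)
    if (is.null(want)) expect_null(got)
    else expect_identical(got, want)
  }
})

test_that("effect_size formula, pseudocount and symmetries", {
  expect_equal(effect_size(20, 100, 10, 100), log2(2.25))
  expect_equal(effect_size(15, 60, 15, 60), 0)
  # antisymmetry
  expect_equal(effect_size(20, 100, 10, 100),
               -effect_size(10, 100, 20, 100))
  # zero cell: pseudocount keeps it finite
  z <- effect_size(0, 50, 10, 100)
  expect_true(is.finite(z)); expect_lt(z, 0)
  expect_error(effect_size(5, 0, 1, 10), "non-empty")
  expect_error(effect_size(11, 10, 1, 10), "0 <= k <= n")
})

test_that("splice-site models score authentic sites above threshold", {
  set.seed(44)
  consensus <- "AAGCAGTAAGTT"       # GT anchor at window positions 6-7
  positives <- vapply(1:100, function(i) {
    b <- strsplit(consensus, "")[[1]]
    flip <- runif(12) < 0.1
    b[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
    b[6] <- "G"; b[7] <- "T"   # keep the anchor
    paste(b, collapse = "")
  }, "")
  background <- vapply(1:300, function(i) random_dna_str(12), "")
  m <- build_ss_model(positives, background, side = "5prime")
  expect_true(all(abs(colSums(m$pwm) - 1) < 1e-9))
  expect_gt(ss_match_score(m, consensus), 2)
  # positives identical: near point masses
  m2 <- build_ss_model(rep(consensus, 60), background)
  expect_gt(max(m2$pwm[, 1]), 0.9)
  # positives drawn from the background distribution: scores center on 0
  m3 <- build_ss_model(background[1:150], background[151:300])
  sc <- ss_match_score(m3, background[1:50])
  expect_lt(abs(mean(sc)), 1)
  expect_error(build_ss_model("ACGT", background), "12 bases")
})

test_that("scan_candidate_ss anchors at dinucleotides and thresholds", {
  set.seed(45)
  consensus <- "AAGCAGTAAGTT"       # GT anchor at window positions 6-7
  positives <- rep(consensus, 60)
  background <- vapply(1:200, function(i) random_dna_str(12), "")
  m <- build_ss_model(positives, background, side = "5prime")
  seq <- paste0(random_dna_str(20), consensus, random_dna_str(20))
  seq <- gsub("GT", "CC", seq)  # remove chance GT anchors...
  seq <- paste0(substr(seq, 1, 20), consensus,
                substr(seq, 33, nchar(seq)))
  hits <- scan_candidate_ss(seq, m)
  expect_true(26L %in% hits$position)   # the planted GT anchor
  # no anchor dinucleotide: empty
  expect_identical(nrow(scan_candidate_ss(strrep("A", 40), m)), 0L)
  # infinite threshold: empty
  expect_identical(nrow(scan_candidate_ss(seq, m, threshold = Inf)), 0L)
})

test_that("junction distance features and frame flags", {
  # internal GT 12 nt downstream of the authentic donor
  iseq <- paste0("GT", strrep("A", 10), "GT", strrep("C", 30), "AG")
  d <- junction_distances(iseq, side = "AltD")
  expect_identical(d$dist_inter, 12L)
  expect_false(d$frame_inter)         # 12 %% 3 == 0: frame-preserving
  expect_identical(d$junction_size, nchar(iseq))
  # internal AG 7 nt upstream of the authentic acceptor
  L <- 40L
  iseq2 <- paste0("GT", strrep("C", L - 4 - 2 - 7), "AG", strrep("C", 5),
                  "AG")
  d2 <- junction_distances(iseq2, side = "AltA")
  expect_identical(d2$dist_inter, 7L)
  expect_true(d2$frame_inter)         # 7 %% 3 != 0: frame-shifting
  # no internal GT: absent state
  d3 <- junction_distances(paste0("GT", strrep("A", 30), "AG"),
                           side = "AltD")
  expect_false(d3$has_inter)
  expect_true(is.na(d3$dist_inter))
})

test_that("hexamer enrichment flags planted motifs and respects the cap", {
  set.seed(46)
  motif <- "GGCGCG"
  pos <- vapply(1:100, function(i) {
    s <- random_dna_str(50)
    if (i <= 80) s <- paste0(substr(s, 1, 20), motif, substr(s, 27, 50))
    s
  }, "")
  bg <- vapply(1:400, function(i) random_dna_str(50), "")
  tab <- hexamer_enrichment(pos, bg)
  row <- tab[tab$motif == motif, ]
  expect_identical(row$direction, "enhancer")
  expect_lt(row$p_adj, 0.01)
  # positives == background: nothing significant
  null_tab <- hexamer_enrichment(bg[1:100], bg[101:400])
  expect_gte(min(null_tab$p_adj), 0.05)
  # background larger than the cap is subsampled to the cap
  tab2 <- hexamer_enrichment(pos, bg, max_background = 150L)
  expect_lte(max(tab2$n_bg), 150L)
  expect_error(hexamer_enrichment(pos[1:5], bg), "at least 10")
})

test_that("feature matrix applies the read and multi-type filters", {
  co <- cached_cohort("featcfg", cohort_config(
    n_genes = 40, seed = 77, as_fraction = 0.3, depth = 60,
    as_type_mix = c(IR = 0.3, AltD = 0.2, AltA = 0.4, ES = 0.1),
    n_species = 1))
  spd <- co$species$sp1
  ev <- classify_species(spd)
  fm <- build_feature_matrix(spd, ev, side = "AltA")
  expect_true(all(fm$label %in% c("alternative", "constitutive")))
  expect_true(all(fm$mean_reads >= 5))
  # every alternative row corresponds to a planted AltA authentic junction
  tr <- co$truth$events[co$truth$events$species == "sp1" &
                          co$truth$events$type == "AltA", ]
  tr_jid <- sprintf("%s:%d-%d:%s", tr$chrom, tr$start, tr$end, tr$strand)
  alt_rows <- fm$junction_id[fm$label == "alternative"]
  expect_true(all(alt_rows %in% tr_jid))
  # a junction below the mean-read threshold is excluded
  spd2 <- spd
  spd2$junctions$reads[spd2$junctions$start ==
                         spd2$junctions$start[1]] <- 2L
  fm2 <- build_feature_matrix(spd2, ev, side = "AltA")
  expect_false(any(fm2$junction_id %in% sprintf(
    "%s:%d-%d:%s", spd$junctions$chrom[1], spd$junctions$start[1],
    spd$junctions$end[1], spd$junctions$strand[1])))
})
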