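# Shared synthetic cohorts, generated once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(name, cfg) {
  if (is.null(.cohort_cache[[name]]))
    .cohort_cache[[name]] <- generate_cohort(cfg)
  .cohort_cache[[name]]
}

# small mixed-type single... two-species cohort for junction/ptc tests
tiny_cohort <- function() {
  cached_cohort("tiny", cohort_config(
    n_genes = 12, seed = 101, as_fraction = 0.4, depth = 100,
    ptc_fraction = 0.5, psi_range = c(0.2, 0.8), psi_divergence = 0.2))
}

# two-species pair cohort for orthology/conservation tests
pair_cohort <- function() {
  cached_cohort("pair", cohort_config(
    n_genes = 20, seed = 202, as_fraction = 0.35, depth = 100,
    divergence = 0.02, psi_range = c(0.2, 0.8), psi_divergence = 0.2))
}

# classify all samples of one species of a cohort
classify_species <- function(spd) {
  classify_as_events(load_junctions(spd$junctions), spd,
                     sample_id = unique(spd$junctions$sample_id))
}

# map each planted event of a two-species cohort to its called
# conservation state (from the first species' perspective)
event_conservation_calls <- function(cohort, labels) {
  tr <- cohort$truth$events
  evs <- unique(tr$event_id)
  got <- vapply(evs, function(eid) {
    r <- tr[tr$event_id == eid, ][1, ]
    jid_a <- sprintf("%s:%d-%d:%s", r$chrom, r$start, r$end, r$strand)
    l <- labels[labels$junction_a == jid_a, ]
    if (!nrow(l)) "unmatched" else l$state[1]
  }, "")
  want <- vapply(evs, function(eid)
    tr$conservation[tr$event_id == eid][1], "")
  data.frame(event_id = evs, want = want, got = got,
             stringsAsFactors = FALSE)
}

# conservation pipeline for a two-species cohort (orthologs, EEJ matches,
# per-sample events, labels); memoised
pair_conservation <- function() {
  if (is.null(.cohort_cache$pair_cons)) {
    co <- pair_cohort()
    a <- co$species$sp1; b <- co$species$sp2
    orth <- find_orthologs(a$proteins, b$proteins)
    eej_a <- build_eej_table(a); eej_b <- build_eej_table(b)
    mm <- match_eejs(eej_a, eej_b, orth)
    ev_a <- classify_species(a); ev_b <- classify_species(b)
    .cohort_cache$pair_cons <- list(
      cohort = co, orth = orth, eej_a = eej_a, eej_b = eej_b,
      matches = mm, events_a = ev_a, events_b = ev_b,
      labels = call_conservation(mm, ev_a, ev_b))
  }
  .cohort_cache$pair_cons
}

# brute-force tract oracle: enumerate every substring of the search
# window and apply the selection rules directly
oracle_tract <- function(intron_seq, kind, window = 50L) {
  x <- toupper(intron_seq); L <- nchar(x)
  if (L < 7L) return(NULL)
  w_end <- L - 2L
  w_start <- max(1L, w_end - window + 1L)
  reg <- substr(x, w_start, w_end)
  good_set <- if (kind == "polypyrimidine") c("C", "T") else c("A", "T")
  n <- nchar(reg)
  best <- NULL
  for (i in seq_len(n)) for (j in seq(i, n)) {
    len <- j - i + 1L
    if (len < 5L) next
    sub <- substr(reg, i, j)
    comp <- mean(strsplit(sub, "")[[1]] %in% good_set)
    if (comp <= 0.85) next
    end_intron <- w_start + j - 1L
    if (kind == "polypyrimidine" && end_intron < L - 9L) next
    cand <- list(start = w_start + i - 1L, end = end_intron,
                 length = len, composition = comp)
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$end > best$end))
      best <- cand
  }
  best
}

# brute-force branch-site oracle
oracle_branch <- function(intron_seq, window = 100L) {
  x <- toupper(intron_seq); L <- nchar(x)
  if (L < 9L) return(NULL)
  w_end <- L - 2L
  w_start <- max(1L, w_end - window + 1L)
  reg <- substr(x, w_start, w_end)
  pats <- list(
    NNYTRAY = function(h) grepl("^..[CT]T[AG]A[CT]$", h),
    NNCTYAC = function(h) grepl("^..CT[CT]AC$", h),
    NNRTAAC = function(h) grepl("^..[AG]TAAC$", h),
    NNCTAAA = function(h) grepl("^..CTAAA$", h))
  hits <- list()
  n <- nchar(reg)
  if (n < 7L) return(NULL)
  for (p in seq_len(n - 6L)) {
    hep <- substr(reg, p, p + 6L)
    if (!any(vapply(pats, function(f) f(hep), logical(1)))) next
    mm <- sum(strsplit(hep, "")[[1]] != strsplit("TACTAAC", "")[[1]])
    hits[[length(hits) + 1L]] <- list(heptamer = hep,
                                      position = w_start + p - 1L,
                                      mismatches = mm)
  }
  if (!length(hits)) return(NULL)
  mms <- vapply(hits, `[[`, 0, "mismatches")
  last <- hits[[length(hits)]]
  if (last$mismatches > min(mms)) return(NULL)
  last
}

# exhaustive pairwise AUC oracle
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

with_seed_local <- function(seed, code) splicevol:::with_seed(seed, code)

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
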