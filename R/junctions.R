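# Junction evidence: loading/filtering, AS event classification, PSI.
#
# Junction intervals are 0-based half-open over the intron.  The donor is
# the 5' intron end on the sense strand: `start` on '+', `end - 1` on '-'.

#' Load and filter a splice-junction table
#'
#' Reads the TSV dialect (`chrom, start, end, strand, reads, min_overhang,
#' intron_coverage[, sample_id]`) or accepts an equivalent data frame.
#' Junctions with overhang below `min_overhang` or intron length outside
#' `intron_bounds` are removed; duplicated junctions (same chrom, start,
#' end, strand and sample) are merged by summing read and coverage counts
#' (keeping the larger overhang).
#'
#' @param x path to a TSV file or a data frame.
#' @param min_overhang minimum accepted overhang in bp (default 13).
#' @param intron_bounds accepted intron length range (default `c(41, 50000)`).
#' @return a data frame of filtered junctions.
#' @export
load_junctions <- function(x, min_overhang = 13L,
                           intron_bounds = c(41L, 50000L)) {
  jx <- if (is.character(x)) {
    if (!file.exists(x)) stopf("junction file does not exist: %s", x)
    utils::read.delim(x, stringsAsFactors = FALSE)
  } else as.data.frame(x)
  if (!("sample_id" %in% names(jx))) jx$sample_id <- "sample1"
  if (!("intron_coverage" %in% names(jx))) jx$intron_coverage <- 0L
  need <- setdiff(JUNCTION_COLS, names(jx))
  if (length(need)) stopf("junction table lacks columns: %s",
                          paste(need, collapse = ", "))
  for (col in c("start", "end", "reads", "min_overhang",
                "intron_coverage")) {
    v <- suppressWarnings(as.integer(jx[[col]]))
    bad <- which(is.na(v) & !is.na(jx[[col]]) | is.na(jx[[col]]))
    if (length(bad)) stopf("malformed %s at line %d", col, bad[1] + 1L)
    jx[[col]] <- v
  }
  if (any(jx$reads < 0)) stopf("negative read count at line %d",
                               which(jx$reads < 0)[1] + 1L)
  if (any(jx$intron_coverage < 0)) stopf("negative intron coverage at line %d",
                                         which(jx$intron_coverage < 0)[1] + 1L)
  if (any(jx$end <= jx$start)) stopf("intron end <= start at line %d",
                                     which(jx$end <= jx$start)[1] + 1L)
  len <- jx$end - jx$start
  keep <- jx$min_overhang >= min_overhang &
    len >= intron_bounds[1] & len <= intron_bounds[2]
  jx <- jx[keep, , drop = FALSE]
  if (nrow(jx)) {
    key <- paste(jx$chrom, jx$start, jx$end, jx$strand, jx$sample_id,
                 sep = "\r")
    if (anyDuplicated(key)) {
      jx <- do.call(rbind, lapply(split(jx, key), function(d) {
        d$reads[1] <- sum(d$reads)
        d$intron_coverage[1] <- sum(d$intron_coverage)
        d$min_overhang[1] <- max(d$min_overhang)
        d[1, , drop = FALSE]
      }))
    }
    jx <- jx[order(jx$sample_id, jx$chrom, jx$start, jx$end), , drop = FALSE]
  }
  rownames(jx) <- NULL
  jx[, JUNCTION_COLS]
}

# assign junctions to genes by coordinate overlap, strand-matched;
# junctions overlapping zero or multiple genes get NA
.assign_genes <- function(jx, genes) {
  if (!nrow(jx)) return(character(0))
  jr <- GenomicRanges::GRanges(jx$chrom,
                               IRanges::IRanges(jx$start + 1L, jx$end),
                               strand = jx$strand)
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end),
                               strand = genes$strand)
  hits <- GenomicRanges::findOverlaps(jr, gr)
  out <- rep(NA_character_, nrow(jx))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  tab <- table(qh)
  uniq <- as.integer(names(tab)[tab == 1L])
  out[uniq] <- genes$gene_id[sh[match(uniq, qh)]]
  out
}

#' Classify AS events from filtered junctions
#'
#' Junctions are assigned to genes by strand-matched coordinate overlap;
#' within each gene, alternative donor (AltD; shared acceptor, differing
#' donor), alternative acceptor (AltA; shared donor, differing acceptor),
#' exon skipping (ES; a junction spanning an exon that a pair of junctions
#' includes) and intron retention (IR; spliced reads plus intronic
#' coverage) events are called.  For AltD/AltA the inclusion isoform is the
#' junction with the shorter intron (more exonic sequence); for IR the
#' inclusion count is the intronic coverage and the exclusion count the
#' spliced junction reads, so that their sum is the event's total support;
#' for ES the inclusion count is the sum of the two inclusion-junction
#' read counts.
#'
#' @param junctions filtered junction data frame (one sample).
#' @param gene_models list with `genes` and `exons` tables (see
#'   [read_gene_models()]).
#' @param sample_id sample label stored on the events.
#' @return data frame of AS events with PSI (NA when total support < 10).
#' @export
classify_as_events <- function(junctions, gene_models,
                               sample_id = junctions$sample_id[1]) {
  if (length(sample_id) > 1L) {
    return(do.call(rbind, lapply(sample_id, function(s)
      classify_as_events(junctions, gene_models, sample_id = s))))
  }
  jx <- junctions[junctions$sample_id %in% sample_id, , drop = FALSE]
  genes <- gene_models$genes
  exons <- gene_models$exons
  if (!nrow(jx)) return(.empty_events())
  jx$gene_id <- .assign_genes(jx, genes)
  skipped <- jx[is.na(jx$gene_id), , drop = FALSE]
  if (nrow(skipped))
    message(sprintf("%d junction(s) overlapped no or multiple genes; skipped",
                    nrow(skipped)))
  jx <- jx[!is.na(jx$gene_id), , drop = FALSE]
  if (!nrow(jx)) return(.empty_events())

  rows <- list()
  add_event <- function(gene_id, type, strand, ja, jb, incl, excl,
                        j2 = c(NA_integer_, NA_integer_)) {
    rows[[length(rows) + 1L]] <<- data.frame(
      event_id = sprintf("%s:%s:%d-%d", gene_id, type, jb[1], jb[2]),
      gene_id = gene_id, type = type, chrom = jx$chrom[1], strand = strand,
      incl_start = jb[1], incl_end = jb[2],
      incl2_start = j2[1], incl2_end = j2[2],
      excl_start = ja[1], excl_end = ja[2],
      inclusion_reads = incl, exclusion_reads = excl,
      total_support = incl + excl,
      psi = compute_psi(incl, excl),
      sample_id = sample_id, stringsAsFactors = FALSE)
  }

  for (gid in unique(jx$gene_id)) {
    g <- jx[jx$gene_id == gid, , drop = FALSE]
    strand <- g$strand[1]
    ex_g <- exons[exons$gene_id == gid, , drop = FALSE]
    # IR: spliced junction with intronic coverage
    ir <- which(g$intron_coverage >= 1L & g$reads >= 0L)
    for (k in ir) {
      add_event(gid, "IR", strand, c(g$start[k], g$end[k]),
                c(g$start[k], g$end[k]),
                incl = g$intron_coverage[k], excl = g$reads[k])
    }
    n <- nrow(g)
    if (n >= 2L) {
      # ES first: a junction spanning an annotated exon that a pair of
      # junctions includes.  Pairs the exclusion junction forms with its
      # inclusion junctions are then suppressed in the AltD/AltA scan.
      suppressed <- matrix(FALSE, n, n)
      for (x in seq_len(n)) {
        j1 <- which(g$start == g$start[x] & g$end < g$end[x])
        j2 <- which(g$end == g$end[x] & g$start > g$start[x])
        for (a in j1) for (b in j2) {
          if (g$end[a] >= g$start[b]) next
          mid <- ex_g[ex_g$start >= g$end[a] & ex_g$end <= g$start[b], ,
                      drop = FALSE]
          if (!nrow(mid)) next
          add_event(gid, "ES", strand,
                    c(g$start[x], g$end[x]),
                    c(g$start[a], g$end[a]),
                    incl = g$reads[a] + g$reads[b], excl = g$reads[x],
                    j2 = c(g$start[b], g$end[b]))
          suppressed[x, a] <- suppressed[a, x] <- TRUE
          suppressed[x, b] <- suppressed[b, x] <- TRUE
        }
      }
      for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
        if (suppressed[a, b]) next
        sa <- g$start[a]; ea <- g$end[a]; sb <- g$start[b]; eb <- g$end[b]
        share_start <- sa == sb && ea != eb
        share_end <- ea == eb && sa != sb
        if (!share_start && !share_end) next
        # donor is the start on '+', the end on '-'
        share_donor <- if (strand == "+") share_start else share_end
        type <- if (share_donor) "AltA" else "AltD"
        len_a <- ea - sa; len_b <- eb - sb
        inc <- if (len_a < len_b) a else b   # shorter intron = inclusion
        exc <- if (len_a < len_b) b else a
        add_event(gid, type, strand,
                  c(g$start[exc], g$end[exc]), c(g$start[inc], g$end[inc]),
                  incl = g$reads[inc], excl = g$reads[exc])
      }
    }
  }
  if (!length(rows)) return(.empty_events())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_events <- function() {
  data.frame(event_id = character(0), gene_id = character(0),
             type = character(0), chrom = character(0), strand = character(0),
             incl_start = integer(0), incl_end = integer(0),
             incl2_start = integer(0), incl2_end = integer(0),
             excl_start = integer(0), excl_end = integer(0),
             inclusion_reads = integer(0), exclusion_reads = integer(0),
             total_support = integer(0), psi = numeric(0),
             sample_id = character(0), stringsAsFactors = FALSE)
}

#' Percent spliced in
#'
#' `PSI = inclusion / (inclusion + exclusion)`, defined only when the total
#' support is at least 10 reads; otherwise `NA`.
#'
#' @param inclusion,exclusion non-negative read counts (vectorised).
#' @return numeric PSI or `NA`.
#' @export
compute_psi <- function(inclusion, exclusion) {
  if (any(inclusion < 0 | exclusion < 0, na.rm = TRUE))
    stopf("read counts must be non-negative")
  total <- inclusion + exclusion
  ifelse(total >= 10L, inclusion / total, NA_real_)
}
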