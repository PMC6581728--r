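# Premature termination codon annotation under the 50-nt rule, and
# AS event classification into AS+PTC / AS-PTC.

#' Longest ATG-initiated open reading frame
#'
#' Scans the forward strand of a mature sequence for the longest
#' ATG-initiated ORF; ties are broken towards the 5'-most start.  An ORF
#' ends at the first in-frame stop codon, or at the transcript end (length
#' truncated to a codon multiple).  Candidate ORFs containing `N` are
#' discarded (conservative).
#'
#' @param mature_sequence character string over A,C,G,T,N.
#' @return `NULL` when no ORF exists, else a list with `start`, `end`
#'   (1-based, inclusive, `end` is the last base of the stop codon when
#'   present), `length`, `has_stop` and `protein` (stop not included).
#' @export
longest_orf <- function(mature_sequence) {
  x <- toupper(mature_sequence)
  n <- nchar(x)
  if (n < 3L) return(NULL)
  b <- strsplit(x, "")[[1]]
  atg <- which(b == "A")
  atg <- atg[atg + 2 <= n & b[atg + 1] == "T" & b[atg + 2] == "G"]
  if (!length(atg)) return(NULL)
  idx <- seq_len(n - 2L)
  cod <- paste0(b[idx], b[idx + 1L], b[idx + 2L])
  stops <- which(cod %in% STOP_CODONS)
  ns <- which(b == "N")
  best <- NULL
  for (s in atg) {
    fs <- stops[stops >= s + 3L & (stops - s) %% 3L == 0L]
    if (length(fs)) {
      end <- fs[1] + 2L; has_stop <- TRUE
    } else {
      end <- s + ((n - s + 1L) %/% 3L) * 3L - 1L; has_stop <- FALSE
    }
    if (length(ns) && any(ns >= s & ns <= end)) next  # N aborts the ORF
    len <- end - s + 1L
    if (is.null(best) || len > best$length)
      best <- list(start = s, end = end, length = len, has_stop = has_stop)
  }
  if (is.null(best)) return(NULL)
  prot_end <- if (best$has_stop) best$end - 3L else best$end
  best$protein <- if (prot_end >= best$start + 2L)
    translate_nt(substr(x, best$start, prot_end)) else ""
  best
}

#' Build a transcript model from genomic exon blocks
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param blocks list of `c(start, end)` 0-based half-open exon blocks in
#'   genomic order.
#' @param strand `"+"` or `"-"`.
#' @param transcript_id identifier.
#' @return list with `transcript_id`, `mature` (sense sequence),
#'   `junctions` (mature coordinates: number of bases 5' of each boundary),
#'   `blocks`, `strand`.
#' @export
build_transcript_model <- function(genome, chrom, blocks, strand,
                                   transcript_id = "tx") {
  blocks <- blocks[order(vapply(blocks, `[[`, 0, 1L))]
  seqs <- vapply(blocks, function(b)
    substr(genome[[chrom]], b[1] + 1L, b[2]), "")
  if (strand == "-") seqs <- rev(vapply(seqs, revcomp, ""))
  mature <- paste(seqs, collapse = "")
  lens <- nchar(seqs)
  juncs <- if (length(lens) > 1L) cumsum(lens)[-length(lens)] else integer(0)
  list(transcript_id = transcript_id, mature = mature,
       junctions = as.integer(juncs), blocks = blocks, strand = strand)
}

#' Annotate a transcript for a premature termination codon (50-nt rule)
#'
#' The transcript has a PTC when the stop codon of its longest ORF lies at
#' least 50 nt upstream of the final exon-exon boundary, measured in
#' mature coordinates from the last base of the stop codon.  With
#' `rule = "any"` the distance is taken to the nearest downstream
#' boundary instead.
#'
#' @param transcript list as from [build_transcript_model()].
#' @param rule `"final"` (default) or `"any"` exon-exon boundary.
#' @return list with `transcript_id`, `has_ptc`,
#'   `distance_to_final_junction` (signed; NA when no ORF/stop or no
#'   junction).
#' @export
annotate_ptc <- function(transcript, rule = c("final", "any")) {
  rule <- match.arg(rule)
  res <- list(transcript_id = transcript$transcript_id, has_ptc = FALSE,
              distance_to_final_junction = NA_real_)
  if (!length(transcript$junctions)) return(res)  # single exon: no PTC
  orf <- longest_orf(transcript$mature)
  if (is.null(orf) || !orf$has_stop) return(res)
  dist <- max(transcript$junctions) - orf$end
  res$distance_to_final_junction <- dist
  if (rule == "final") {
    res$has_ptc <- dist >= 50
  } else {
    dn <- transcript$junctions[transcript$junctions > orf$end]
    res$has_ptc <- length(dn) > 0 && any(dn - orf$end >= 50)
  }
  res
}

# structural difference between two transcripts confined to one interval?
.blocks_diff_confined <- function(blocks_a, blocks_b, lo, hi) {
  key <- function(blocks) vapply(blocks, function(b)
    paste0(b[1], "-", b[2]), "")
  ka <- key(blocks_a); kb <- key(blocks_b)
  only_a <- blocks_a[!(ka %in% kb)]
  only_b <- blocks_b[!(kb %in% ka)]
  inside <- function(bl) all(vapply(bl, function(b)
    b[2] >= lo & b[1] <= hi, logical(1)))
  inside(only_a) && inside(only_b)
}

#' Classify an AS event as AS+PTC / AS-PTC
#'
#' A class is assigned only when the event maps to exactly two transcripts
#' whose sole structural difference is the AS region, and at least one of
#' them lacks a PTC.  Events whose two transcripts both carry PTCs are
#' excluded (likely annotation artefacts), as are events mapping to any
#' other number of transcripts.
#'
#' @param event one-row data frame (or list) with `excl_start`, `excl_end`
#'   delimiting the AS region.
#' @param transcripts list of transcript models with `event_id` fields
#'   attached, or a pre-filtered list of the event's transcripts.
#' @param ptc_status optional list of [annotate_ptc()] results parallel to
#'   `transcripts` (computed when missing).
#' @return one of `"AS_plus_PTC"`, `"AS_minus_PTC"`, `"unassigned"`.
#' @export
classify_event_ptc <- function(event, transcripts, ptc_status = NULL) {
  if (length(transcripts) != 2L) return("unassigned")
  lo <- min(event$excl_start, event$incl_start %||% event$excl_start)
  hi <- max(event$excl_end, event$incl_end %||% event$excl_end)
  if (!.blocks_diff_confined(transcripts[[1]]$blocks,
                             transcripts[[2]]$blocks, lo, hi))
    return("unassigned")
  if (is.null(ptc_status))
    ptc_status <- lapply(transcripts, annotate_ptc)
  ptc <- vapply(ptc_status, function(p) isTRUE(p$has_ptc), logical(1))
  if (all(ptc)) return("unassigned")   # two PTC+ transcripts: excluded
  if (any(ptc)) "AS_plus_PTC" else "AS_minus_PTC"
}

#' Compare conservation of AS+PTC vs AS-PTC events
#'
#' Builds the 2x2 contingency table (PTC class x conserved-or-not) and
#' reports the sample odds ratio and the two-sided Fisher exact test
#' p-value.
#'
#' @param ptc_class character vector, `"AS_plus_PTC"`/`"AS_minus_PTC"`.
#' @param conserved logical vector parallel to `ptc_class`.
#' @return list with `table` (2x2), `odds_ratio`, `p_value`.
#' @export
compare_ptc_conservation <- function(ptc_class, conserved = NULL) {
  if (is.matrix(ptc_class)) {
    tab <- ptc_class
    stopifnot(all(dim(tab) == c(2L, 2L)))
  } else {
    keep <- ptc_class %in% c("AS_plus_PTC", "AS_minus_PTC")
    ptc_class <- factor(ptc_class[keep],
                        levels = c("AS_plus_PTC", "AS_minus_PTC"))
    conserved <- factor(ifelse(conserved[keep], "conserved",
                               "not_conserved"),
                        levels = c("conserved", "not_conserved"))
    tab <- table(ptc_class, conserved)
  }
  if (sum(tab) == 0L) stopf("all-zero contingency table")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c)
  p <- fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p_value = p)
}
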