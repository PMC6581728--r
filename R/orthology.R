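# Cross-species orthology of genes and exon-exon junctions (EEJs).
#
# Gene orthologs: reciprocal best hits by local protein alignment
# (BLOSUM62, affine gaps) with a Karlin-Altschul style significance proxy.
# EEJ matching: each junction is represented by up to 100 bp of flanking
# exonic sequence on each side (sense strand); candidate pairs within
# ortholog gene pairs are compared by translated local alignment and must
# be reciprocal best and pass the alignment filters.

.pkg_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

.protein_scores <- function(pats, subj) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(pats),
    subject = subj, type = "local",
    substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
}

#' Identify one-to-one orthologous genes by reciprocal best hit
#'
#' All-against-all local protein alignment; a gene pair is kept when each
#' member is the unique best hit of the other and the significance proxy
#' passes `evalue_max`.  Ties for best hit exclude the gene (one-to-one
#' means unique).
#'
#' @param proteins_a,proteins_b named character vectors, `AAStringSet`s or
#'   FASTA paths of protein sequences (names are gene ids).
#' @param evalue_max significance threshold (default 1e-6).
#' @return data frame with `gene_a`, `gene_b`, `score`, `evalue`.
#' @export
find_orthologs <- function(proteins_a, proteins_b, evalue_max = 1e-6) {
  pa <- .as_aa(proteins_a); pb <- .as_aa(proteins_b)
  if (!length(pa) || !length(pb)) {
    warning("empty protein set; no orthologs")
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), evalue = numeric(0)))
  }
  score <- matrix(0, length(pa), length(pb),
                  dimnames = list(names(pa), names(pb)))
  for (j in seq_along(pb)) {
    score[, j] <- .protein_scores(pa, pb[[j]])
  }
  m <- sum(Biostrings::width(pa)); n <- sum(Biostrings::width(pb))
  eval_mat <- ka_evalue(score, m, n)
  ok <- eval_mat <= evalue_max
  best_a <- apply(score, 1L, function(r) {
    w <- which(r == max(r))
    if (length(w) == 1L) w else NA_integer_
  })
  best_b <- apply(score, 2L, function(r) {
    w <- which(r == max(r))
    if (length(w) == 1L) w else NA_integer_
  })
  rows <- list()
  for (i in seq_along(pa)) {
    j <- best_a[i]
    if (is.na(j) || !ok[i, j]) next
    if (!is.na(best_b[j]) && best_b[j] == i) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = names(pa)[i], gene_b = names(pb)[j],
        score = score[i, j], evalue = eval_mat[i, j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(gene_a = character(0),
                                       gene_b = character(0),
                                       score = numeric(0),
                                       evalue = numeric(0)))
  do.call(rbind, rows)
}

.as_aa <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readAAStringSet(x)
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  setNames(x, sub("\\s.*", "", names(x)))
}

#' Extract the exonic flanking sequence of a junction (EEJ sequence)
#'
#' Up to 100 bp of exonic sequence from the flanking upstream and
#' downstream exon of the junction, truncated at exon boundaries, on the
#' sense strand (minus-strand genes are reverse-complemented).
#'
#' @param genome named character vector of chromosome sequences.
#' @param gene_model list with `exons` table for the gene.
#' @param junction list or one-row data frame with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open intron).
#' @param flank maximum flank width (default 100).
#' @return list with `up`, `down`, `seq`, `len_up`, `len_down`.
#' @export
extract_eej_sequence <- function(genome, gene_model, junction, flank = 100L) {
  ex <- gene_model$exons
  js <- junction$start; je <- junction$end; strand <- junction$strand
  chrom <- junction$chrom
  left <- ex[ex$end == js, , drop = FALSE]    # exon ending at intron start
  right <- ex[ex$start == je, , drop = FALSE] # exon starting at intron end
  if (!nrow(left) || !nrow(right))
    stopf("junction %s:%d-%d has no flanking annotated exons",
          chrom, js, je)
  left <- left[1, ]; right <- right[1, ]
  take_left <- min(flank, left$end - left$start)
  take_right <- min(flank, right$end - right$start)
  seq_chr <- genome[[chrom]]
  lseq <- substr(seq_chr, js - take_left + 1L, js)
  rseq <- substr(seq_chr, je + 1L, je + take_right)
  if (strand == "+") {
    list(up = lseq, down = rseq, seq = paste0(lseq, rseq),
         len_up = nchar(lseq), len_down = nchar(rseq))
  } else {
    up <- revcomp(rseq); down <- revcomp(lseq)
    list(up = up, down = down, seq = paste0(up, down),
         len_up = nchar(up), len_down = nchar(down))
  }
}

.three_frames <- function(s) {
  lapply(0:2, function(f) {
    list(frame = f, aa = translate_nt(substr(s, f + 1L, nchar(s))))
  })
}

# best translated local-alignment score for every pair of sequences,
# vectorised over patterns (score only)
.frame_score_matrix <- function(seqs_a, seqs_b) {
  fa <- lapply(seqs_a, .three_frames)
  fb <- lapply(seqs_b, .three_frames)
  # flatten A frames into one pattern set, remembering owners
  pat <- character(0); owner <- integer(0)
  for (i in seq_along(fa)) for (x in fa[[i]]) {
    if (nchar(x$aa) >= 3L) { pat <- c(pat, x$aa); owner <- c(owner, i) }
  }
  sc <- matrix(-Inf, length(seqs_a), length(seqs_b))
  if (!length(pat)) return(sc)
  pat_set <- Biostrings::AAStringSet(pat)
  for (j in seq_along(fb)) {
    for (x in fb[[j]]) {
      if (nchar(x$aa) < 3L) next
      s <- Biostrings::pairwiseAlignment(
        pattern = pat_set, subject = x$aa, type = "local",
        substitutionMatrix = .blosum62(), gapOpening = 11,
        gapExtension = 1, scoreOnly = TRUE)
      for (i in seq_along(seqs_a)) {
        mx <- suppressWarnings(max(s[owner == i]))
        if (mx > sc[i, j]) sc[i, j] <- mx
      }
    }
  }
  sc
}

# translated comparison of two EEJ sequences over frame combinations;
# returns best score with footprint statistics, or NULL
.translated_match <- function(sa, sb, len_up_a, len_up_b) {
  fa <- .three_frames(sa); fb <- .three_frames(sb)
  best <- NULL
  for (xa in fa) for (xb in fb) {
    if (nchar(xa$aa) < 3L || nchar(xb$aa) < 3L) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = xa$aa, subject = xb$aa, type = "local",
      substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(aln)
    if (!is.null(best) && sc <= best$score) next
    # aligned (non-gap) amino-acid positions in each sequence
    pos_a <- .aligned_positions(aln, "pattern")
    pos_b <- .aligned_positions(aln, "subject")
    # nucleotide footprint of an aa position p (1-based):
    # [frame + 3p - 2, frame + 3p]
    nt_a <- lapply(pos_a, function(p) xa$frame + c(3L * p - 2L, 3L * p))
    nt_b <- lapply(pos_b, function(p) xb$frame + c(3L * p - 2L, 3L * p))
    count_flank <- function(nt, len_up, side) {
      sum(vapply(nt, function(r) {
        if (side == "up") r[2] <= len_up else r[1] >= len_up + 1L
      }, logical(1)))
    }
    aa_up <- min(count_flank(nt_a, len_up_a, "up"),
                 count_flank(nt_b, len_up_b, "up"))
    aa_down <- min(count_flank(nt_a, len_up_a, "down"),
                   count_flank(nt_b, len_up_b, "down"))
    best <- list(score = sc, n_aligned_aa = length(pos_a),
                 coverage_bp = 3L * length(pos_a),
                 aa_up = aa_up, aa_down = aa_down)
  }
  best
}

# 1-based positions of non-gap-aligned residues of pattern/subject
.aligned_positions <- function(aln, which = c("pattern", "subject")) {
  which <- match.arg(which)
  al <- if (which == "pattern") Biostrings::pattern(aln) else
    Biostrings::subject(aln)
  chars_p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  chars_s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  st <- Biostrings::start(al)
  chars <- if (which == "pattern") chars_p else chars_s
  other <- if (which == "pattern") chars_s else chars_p
  pos <- integer(0); cur <- st - 1L
  for (k in seq_along(chars)) {
    if (chars[k] != "-") cur <- cur + 1L
    if (chars[k] != "-" && other[k] != "-") pos <- c(pos, cur)
  }
  pos
}

#' Match exon-exon junctions between two species
#'
#' Candidate pairs are restricted to one-to-one ortholog gene pairs;
#' translated local alignment of the combined flank sequences over all
#' frame combinations; reciprocal best within the gene pair by score;
#' filters: at least `min_aa_flank` aligned amino acids on both flanks,
#' aligned coverage at least `min_coverage_bp`, significance proxy below
#' `evalue_max`.
#'
#' @param eejs_a,eejs_b data frames with one row per junction: `junction_id`,
#'   `gene_id`, `seq`, `len_up`, `len_down` (see [extract_eej_sequence()]).
#' @param ortholog_pairs data frame with `gene_a`, `gene_b`.
#' @param min_aa_flank,min_coverage_bp,evalue_max filter thresholds.
#' @return data frame of accepted matches.
#' @export
match_eejs <- function(eejs_a, eejs_b, ortholog_pairs,
                       min_aa_flank = 3L, min_coverage_bp = 60L,
                       evalue_max = 1e-3) {
  rows <- list()
  m_tot <- sum(nchar(eejs_a$seq)); n_tot <- sum(nchar(eejs_b$seq))
  for (k in seq_len(nrow(ortholog_pairs))) {
    ga <- ortholog_pairs$gene_a[k]; gb <- ortholog_pairs$gene_b[k]
    ea <- eejs_a[eejs_a$gene_id == ga, , drop = FALSE]
    eb <- eejs_b[eejs_b$gene_id == gb, , drop = FALSE]
    if (!nrow(ea) || !nrow(eb)) next
    sc <- .frame_score_matrix(ea$seq, eb$seq)
    for (i in seq_len(nrow(ea))) {
      j <- which.max(sc[i, ])
      if (!is.finite(sc[i, j])) next
      if (which.max(sc[, j]) != i) next          # reciprocal best
      r <- .translated_match(ea$seq[i], eb$seq[j],
                             ea$len_up[i], eb$len_up[j])
      if (is.null(r)) next
      ev <- ka_evalue(r$score, m_tot / 3, n_tot / 3)
      if (r$aa_up < min_aa_flank || r$aa_down < min_aa_flank) next
      if (r$coverage_bp < min_coverage_bp) next
      if (ev > evalue_max) next
      rows[[length(rows) + 1L]] <- data.frame(
        junction_a = ea$junction_id[i], junction_b = eb$junction_id[j],
        gene_a = ga, gene_b = gb,
        aligned_aa_up = r$aa_up, aligned_aa_down = r$aa_down,
        coverage_bp = r$coverage_bp, score = r$score, evalue = ev,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(junction_a = character(0), junction_b = character(0),
                      gene_a = character(0), gene_b = character(0),
                      aligned_aa_up = integer(0),
                      aligned_aa_down = integer(0),
                      coverage_bp = integer(0), score = numeric(0),
                      evalue = numeric(0)))
  do.call(rbind, rows)
}

#' Build the EEJ table of a species for matching
#'
#' Extracts flank sequences for every distinct junction with read support.
#'
#' @param species_data list with `genome`, `genes`, `exons`, `junctions`.
#' @param flank flank width (default 100).
#' @return data frame with `junction_id`, `gene_id`, coordinates, `seq`,
#'   `len_up`, `len_down`.
#' @export
build_eej_table <- function(species_data, flank = 100L) {
  jx <- unique(species_data$junctions[
    species_data$junctions$reads > 0,
    c("chrom", "start", "end", "strand")])
  jx$gene_id <- .assign_genes(jx, species_data$genes)
  jx <- jx[!is.na(jx$gene_id), , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(jx))) {
    gm <- list(exons = species_data$exons[
      species_data$exons$gene_id == jx$gene_id[k], , drop = FALSE])
    eej <- tryCatch(
      extract_eej_sequence(species_data$genome, gm, jx[k, ], flank = flank),
      error = function(e) NULL)
    if (is.null(eej)) next
    rows[[length(rows) + 1L]] <- data.frame(
      junction_id = sprintf("%s:%d-%d:%s", jx$chrom[k], jx$start[k],
                            jx$end[k], jx$strand[k]),
      gene_id = jx$gene_id[k], chrom = jx$chrom[k],
      start = jx$start[k], end = jx$end[k], strand = jx$strand[k],
      seq = eej$seq, len_up = eej$len_up, len_down = eej$len_down,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(junction_id = character(0), gene_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0), len_up = integer(0),
                      len_down = integer(0)))
  do.call(rbind, rows)
}

AS_STATES <- c("none", "AltA", "AltD", "ES", "IR")

# AS types present per junction id, from a classified event table
.junction_types <- function(events, eejs) {
  types <- list()
  note <- function(jid, type) {
    if (is.null(types[[jid]])) types[[jid]] <<- character(0)
    types[[jid]] <<- union(types[[jid]], type)
  }
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    jid_in <- sprintf("%s:%d-%d:%s", e$chrom, e$incl_start, e$incl_end,
                      e$strand)
    jid_ex <- sprintf("%s:%d-%d:%s", e$chrom, e$excl_start, e$excl_end,
                      e$strand)
    note(jid_in, e$type)
    note(jid_ex, e$type)
    if (!is.na(e$incl2_start)) {
      note(sprintf("%s:%d-%d:%s", e$chrom, e$incl2_start, e$incl2_end,
                   e$strand), e$type)
    }
  }
  types
}

#' Call AS conservation at matched EEJs
#'
#' A matched pair is `conserved` when the same AS type is present on both
#' sides, `lost` when AS is present only in the first species, `gained`
#' when only in the second, `type_switch` when the types differ, `none`
#' when neither side has AS.  EEJs carrying more than one AS type are
#' excluded.
#'
#' @param matches output of [match_eejs()].
#' @param events_a,events_b classified event tables of the two species.
#' @return data frame of conservation labels.
#' @export
call_conservation <- function(matches, events_a, events_b) {
  ta <- .junction_types(events_a, NULL)
  tb <- .junction_types(events_b, NULL)
  rows <- list()
  for (k in seq_len(nrow(matches))) {
    ja <- matches$junction_a[k]; jb <- matches$junction_b[k]
    tya <- ta[[ja]] %||% character(0)
    tyb <- tb[[jb]] %||% character(0)
    if (length(tya) > 1L || length(tyb) > 1L) next  # multi-type EEJ excluded
    a <- if (length(tya)) tya else "none"
    b <- if (length(tyb)) tyb else "none"
    state <- if (a == "none" && b == "none") "none"
      else if (a == b) "conserved"
      else if (b == "none") "lost"
      else if (a == "none") "gained"
      else sprintf("type_switch(%s->%s)", a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      junction_a = ja, junction_b = jb, state = state,
      as_type_a = a, as_type_b = b, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(junction_a = character(0), junction_b = character(0),
                      state = character(0), as_type_a = character(0),
                      as_type_b = character(0)))
  do.call(rbind, rows)
}

#' AS transition spectrum between two species
#'
#' 5x5 count matrix over \{none, AltA, AltD, ES, IR\} for matched EEJ
#' pairs; rows are the first species' state, columns the second's.  The
#' grand total equals the number of labeled pairs.
#'
#' @param labels output of [call_conservation()].
#' @return integer matrix with dimnames over the five states.
#' @export
transition_spectrum <- function(labels) {
  m <- table(factor(labels$as_type_a, levels = AS_STATES),
             factor(labels$as_type_b, levels = AS_STATES))
  mat <- matrix(as.integer(m), 5L, 5L,
                dimnames = list(AS_STATES, AS_STATES))
  mat
}
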