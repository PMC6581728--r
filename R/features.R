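# Splice-site determinant features: 12-mer splice-site models and
# match-score scanning, alternative splice-site / inter-GT/AG distances,
# polypyrimidine and UA tracts, branch sites, effect sizes, and hexamer
# enrichment.

#' Intron sequence on the sense strand
#'
#' @param genome named character vector of chromosome sequences.
#' @param junction list/row with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @return character string beginning GT and ending AG for canonical
#'   introns.
#' @export
intron_sequence <- function(genome, junction) {
  s <- substr(genome[[junction$chrom]], junction$start + 1L, junction$end)
  if (junction$strand == "-") revcomp(s) else s
}

#' Build a 12-mer splice-site model (PWM)
#'
#' The window is 5 bp upstream + the site dinucleotide + 5 bp downstream
#' (12 bases).  Column probabilities use a Laplace pseudocount of 1; the
#' background is the overall base composition of the background windows.
#' Match scores are summed per-position log2 odds against the background.
#'
#' @param positives character vector of 12-mers at authentic sites.
#' @param background character vector of 12-mers at inter-GT/AG decoys (or
#'   any background sample).
#' @param side `"5prime"` or `"3prime"`.
#' @return object of class `ss_model` with `pwm` (4 x 12), `bg`, `side`.
#' @export
build_ss_model <- function(positives, background, side = "5prime") {
  if (length(positives) < 1L) stopf("no positive sequences")
  if (any(nchar(positives) != 12L) || any(nchar(background) != 12L))
    stopf("splice-site windows must be exactly 12 bases")
  mat <- do.call(rbind, strsplit(toupper(positives), ""))
  pwm <- sapply(seq_len(12L), function(j) {
    cnt <- table(factor(mat[, j], levels = DNA_BASES)) + 1  # pseudocount
    as.numeric(cnt / sum(cnt))
  })
  rownames(pwm) <- DNA_BASES
  bg_bases <- unlist(strsplit(toupper(background), ""))
  bg_cnt <- table(factor(bg_bases, levels = DNA_BASES)) + 1
  bg <- as.numeric(bg_cnt / sum(bg_cnt))
  names(bg) <- DNA_BASES
  structure(list(pwm = pwm, bg = bg, side = side), class = "ss_model")
}

#' Score a 12-mer against a splice-site model
#'
#' @param model an `ss_model`.
#' @param window 12-base string (vectorised).
#' @return numeric log2-odds match score(s).
#' @export
ss_match_score <- function(model, window) {
  vapply(window, function(w) {
    b <- strsplit(toupper(w), "")[[1]]
    if (length(b) != 12L) return(NA_real_)
    i <- match(b, DNA_BASES)
    if (anyNA(i)) return(NA_real_)
    sum(log2(model$pwm[cbind(i, seq_len(12L))] / model$bg[i]))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan a sequence for candidate splice sites
#'
#' Positions are anchored at GT (5' model) or AG (3' model) dinucleotides;
#' the surrounding 12-mer is scored and positions with match score above
#' `threshold` are returned.
#'
#' @param sequence sense-strand sequence.
#' @param model an `ss_model`.
#' @param threshold minimum retained match score (default 2).
#' @return data frame with `position` (1-based position of the first base
#'   of the dinucleotide), `score`.
#' @export
scan_candidate_ss <- function(sequence, model, threshold = 2) {
  x <- toupper(sequence)
  n <- nchar(x)
  anchor <- if (model$side == "5prime") "GT" else "AG"
  if (n < 12L)
    return(data.frame(position = integer(0), score = numeric(0)))
  b <- strsplit(x, "")[[1]]
  pos <- which(b[-n] == substr(anchor, 1, 1) &
               b[-1] == substr(anchor, 2, 2))
  pos <- pos[pos >= 6L & pos + 6L <= n]
  if (!length(pos))
    return(data.frame(position = integer(0), score = numeric(0)))
  win <- substring(x, pos - 5L, pos + 6L)
  sc <- ss_match_score(model, win)
  keep <- !is.na(sc) & sc > threshold
  data.frame(position = pos[keep], score = sc[keep])
}

#' Distance features of a junction
#'
#' Computed on the sense-strand intron sequence.  The authentic donor is
#' the GT at intron positions 1-2 and the authentic acceptor the AG at the
#' last two positions.  For side `"AltD"` the internal competitors are GT
#' dinucleotides (and PWM-passing candidate donor sites when a model is
#' given); for `"AltA"`, AG dinucleotides / candidate acceptors.
#' Distances are measured in nt between the authentic and the competitor
#' dinucleotide start; a frame-shift flag is `distance %% 3 != 0`.
#'
#' @param intron_seq sense intron sequence (GT..AG).
#' @param side `"AltD"` or `"AltA"`.
#' @param model optional `ss_model` for candidate splice sites.
#' @param threshold match-score threshold for candidates.
#' @return list with `junction_size`, `dist_inter` (nearest internal
#'   GT/AG), `frame_inter`, `has_inter`, `dist_alt_ss`, `frame_alt_ss`,
#'   `has_alt_ss`.
#' @export
junction_distances <- function(intron_seq, side = c("AltD", "AltA"),
                               model = NULL, threshold = 2) {
  side <- match.arg(side)
  x <- toupper(intron_seq)
  L <- nchar(x)
  b <- strsplit(x, "")[[1]]
  din <- if (side == "AltD") "GT" else "AG"
  pos <- which(b[-L] == substr(din, 1, 1) & b[-1] == substr(din, 2, 2))
  if (side == "AltD") {
    pos <- setdiff(pos, 1L)                 # authentic donor
    dists <- pos - 1L
  } else {
    pos <- setdiff(pos, L - 1L)             # authentic acceptor
    dists <- (L - 1L) - pos
  }
  dists <- dists[dists >= 1L]
  out <- list(junction_size = L,
              has_inter = length(dists) > 0,
              dist_inter = if (length(dists)) min(dists) else NA_integer_,
              frame_inter = if (length(dists)) (min(dists) %% 3L) != 0L
                else NA,
              has_alt_ss = FALSE, dist_alt_ss = NA_integer_,
              frame_alt_ss = NA)
  if (!is.null(model)) {
    cand <- scan_candidate_ss(x, model, threshold)
    cpos <- cand$position
    cd <- if (side == "AltD") cpos - 1L else (L - 1L) - cpos
    cd <- cd[cd >= 1L]
    if (length(cd)) {
      out$has_alt_ss <- TRUE
      out$dist_alt_ss <- min(cd)
      out$frame_alt_ss <- (min(cd) %% 3L) != 0L
    }
  }
  out
}

#' Find the polypyrimidine / UA tract of an intron
#'
#' The last `window` intronic bases upstream of the acceptor AG are
#' searched for the longest substring of length >= 5 whose C+T (for
#' `polypyrimidine`) or A+T (for `UA`) composition strictly exceeds 0.85.
#' Polypyrimidine tracts must additionally end within the last 10 bases of
#' the intron.  Ties on length are broken towards the 3'-most hit.
#'
#' @param intron_seq sense intron sequence.
#' @param kind `"polypyrimidine"` or `"UA"`.
#' @param window search window size (default 50).
#' @return `NULL` or list with `kind`, `start`, `end` (1-based intron
#'   coordinates), `length`, `composition`.
#' @export
find_tract <- function(intron_seq, kind = c("polypyrimidine", "UA"),
                       window = 50L) {
  kind <- match.arg(kind)
  x <- toupper(intron_seq)
  L <- nchar(x)
  if (L < 7L) return(NULL)
  w_end <- L - 2L                       # terminal AG excluded
  w_start <- max(1L, w_end - window + 1L)
  b <- strsplit(substr(x, w_start, w_end), "")[[1]]
  good <- b %in% (if (kind == "polypyrimidine") c("C", "T") else c("A", "T"))
  n <- length(b)
  best <- NULL
  for (i in seq_len(n)) {
    cum <- cumsum(good[i:n])
    lens <- seq_len(n - i + 1L)
    comp <- cum / lens
    ok <- which(lens >= 5L & comp > 0.85)
    if (!length(ok)) next
    for (k in ok) {
      j <- i + k - 1L
      end_intron <- w_start + j - 1L
      if (kind == "polypyrimidine" && end_intron < L - 9L) next
      cand <- list(kind = kind, start = w_start + i - 1L,
                   end = end_intron, length = k, composition = comp[k])
      if (is.null(best) || cand$length > best$length ||
          (cand$length == best$length && cand$end > best$end))
        best <- cand
    }
  }
  best
}

BRANCH_PATTERNS <- c("NNYTRAY", "NNCTYAC", "NNRTAAC", "NNCTAAA")
BRANCH_CONSENSUS <- "TACTAAC"

#' Find the branch site of an intron
#'
#' The last 100 intronic nt upstream of the acceptor AG are scanned for
#' heptamers matching any of `NNYTRAY`, `NNCTYAC`, `NNRTAAC`, `NNCTAAA`
#' (IUPAC).  Each hit is scored by its number of mismatches to the optimal
#' consensus `TACTAAC`.  The intron is reported only when its most
#' downstream hit also has the (tied-or-) best score; otherwise `NULL`.
#'
#' @param intron_seq sense intron sequence.
#' @param window scan window (default 100).
#' @return `NULL` or list with `heptamer`, `position` (1-based start in
#'   intron coordinates), `mismatches`.
#' @export
find_branch_site <- function(intron_seq, window = 100L) {
  x <- toupper(intron_seq)
  L <- nchar(x)
  if (L < 9L) return(NULL)
  w_end <- L - 2L
  w_start <- max(1L, w_end - window + 1L)
  reg <- substr(x, w_start, w_end)
  n <- nchar(reg)
  if (n < 7L) return(NULL)
  hits <- list()
  for (p in seq_len(n - 6L)) {
    hep <- substr(reg, p, p + 6L)
    if (!any(vapply(BRANCH_PATTERNS, iupac_match, logical(1), x = hep)))
      next
    mm <- sum(strsplit(hep, "")[[1]] !=
              strsplit(BRANCH_CONSENSUS, "")[[1]])
    hits[[length(hits) + 1L]] <- list(heptamer = hep,
                                      position = w_start + p - 1L,
                                      mismatches = mm)
  }
  if (!length(hits)) return(NULL)
  mms <- vapply(hits, `[[`, 0, "mismatches")
  last <- hits[[length(hits)]]        # most downstream
  if (last$mismatches > min(mms)) return(NULL)
  last
}

#' Log2 odds-ratio effect size of a motif/tract on AS frequency
#'
#' `log2( [p(AS|motif)/(1-p(AS|motif))] / [p(AS|-motif)/(1-p(AS|-motif))] )`.
#' When any cell of the 2x2 table is zero, 0.5 is added to all cells.
#'
#' @param k_with,n_with AS and total junction counts with the motif.
#' @param k_without,n_without counts without the motif.
#' @return numeric effect size (log2 odds ratio).
#' @export
effect_size <- function(k_with, n_with, k_without, n_without) {
  if (n_with <= 0 || n_without <= 0) stopf("both groups must be non-empty")
  if (k_with < 0 || k_with > n_with || k_without < 0 ||
      k_without > n_without)
    stopf("counts must satisfy 0 <= k <= n")
  a <- k_with; b <- n_with - k_with
  c <- k_without; d <- n_without - k_without
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  log2((a / b) / (c / d))
}

#' Hexamer (6-mer) enrichment between positive and background windows
#'
#' Presence/absence of each 6-mer per window; hypergeometric enrichment
#' test in both directions, BH-adjusted.  Motifs enriched in positives are
#' putative enhancers; motifs enriched in the background are putative
#' silencers.  Backgrounds larger than `max_background` are subsampled
#' (seeded).
#'
#' @param positive,background character vectors of sequence windows.
#' @param max_background background subsample cap (default 10000).
#' @param seed subsampling seed.
#' @return data frame: `motif`, `n_pos`, `n_bg`, `p_value`, `p_adj`,
#'   `direction`, sorted by adjusted p-value.
#' @export
hexamer_enrichment <- function(positive, background, max_background = 10000L,
                               seed = 1L) {
  if (length(positive) < 10L || length(background) < 10L)
    stopf("need at least 10 windows per side")
  if (length(background) > max_background) {
    background <- with_seed(derive_seed(seed, 17L),
                            sample(background, max_background))
  }
  kmers_of <- function(s) {
    s <- toupper(s); n <- nchar(s)
    if (n < 6L) return(character(0))
    unique(substring(s, seq_len(n - 5L), seq.int(6L, n)))
  }
  pos_sets <- lapply(positive, kmers_of)
  bg_sets <- lapply(background, kmers_of)
  pos_tab <- table(unlist(pos_sets))
  bg_tab <- table(unlist(bg_sets))
  motifs <- union(names(pos_tab), names(bg_tab))
  Np <- length(positive); Nb <- length(background)
  n_pos <- as.integer(pos_tab[motifs]); n_pos[is.na(n_pos)] <- 0L
  n_bg <- as.integer(bg_tab[motifs]); n_bg[is.na(n_bg)] <- 0L
  # hypergeometric: white = windows containing the motif, draw = positives
  p_enh <- phyper(n_pos - 1L, n_pos + n_bg, Np + Nb - n_pos - n_bg, Np,
                  lower.tail = FALSE)
  p_sil <- phyper(n_pos, n_pos + n_bg, Np + Nb - n_pos - n_bg, Np,
                  lower.tail = TRUE)
  direction <- ifelse(p_enh <= p_sil, "enhancer", "silencer")
  p <- pmin(1, 2 * pmin(p_enh, p_sil))
  out <- data.frame(motif = motifs, n_pos = n_pos, n_bg = n_bg,
                    p_value = p, p_adj = p.adjust(p, "BH"),
                    direction = direction, stringsAsFactors = FALSE)
  out[order(out$p_adj, out$p_value), ]
}

# 12-mer windows at the authentic sites and inter-GT/AG decoys of a set of
# intron sequences (sense strand, with 5 exonic bases on the outer side
# supplied via flanks).
.site_windows <- function(intron_seq, up_exon, down_exon) {
  # donor window: last 5 exon bases + GT + next 5 intron bases
  don <- paste0(substr(up_exon, nchar(up_exon) - 4L, nchar(up_exon)),
                substr(intron_seq, 1L, 7L))
  L <- nchar(intron_seq)
  acc <- paste0(substr(intron_seq, L - 6L, L),
                substr(down_exon, 1L, 5L))
  list(donor = don, acceptor = acc)
}

#' Build splice-site models from a species' junctions
#'
#' Positive windows are the 12-mers around every authentic donor/acceptor;
#' background windows are sampled around internal GT/AG dinucleotides of
#' the same introns.
#'
#' @param species_data list with `genome`, `genes`, `exons`, `junctions`.
#' @param max_sites cap on junctions used (default 2000).
#' @return list with `donor` and `acceptor` `ss_model`s.
#' @export
build_species_ss_models <- function(species_data, max_sites = 2000L) {
  jx <- unique(species_data$junctions[, c("chrom", "start", "end",
                                          "strand")])
  if (nrow(jx) > max_sites) jx <- jx[seq_len(max_sites), ]
  don_pos <- character(0); acc_pos <- character(0)
  don_bg <- character(0); acc_bg <- character(0)
  for (k in seq_len(nrow(jx))) {
    iseq <- intron_sequence(species_data$genome, jx[k, ])
    L <- nchar(iseq)
    if (L < 20L) next
    if (substr(iseq, 1, 2) != "GT" || substr(iseq, L - 1, L) != "AG") next
    # exonic context from the genome directly (5 bases beyond the intron)
    gseq <- species_data$genome[[jx$chrom[k]]]
    if (jx$strand[k] == "+") {
      upe <- substr(gseq, jx$start[k] - 4L, jx$start[k])
      dne <- substr(gseq, jx$end[k] + 1L, jx$end[k] + 5L)
    } else {
      upe <- revcomp(substr(gseq, jx$end[k] + 1L, jx$end[k] + 5L))
      dne <- revcomp(substr(gseq, jx$start[k] - 4L, jx$start[k]))
    }
    w <- .site_windows(iseq, upe, dne)
    if (nchar(w$donor) == 12L) don_pos <- c(don_pos, w$donor)
    if (nchar(w$acceptor) == 12L) acc_pos <- c(acc_pos, w$acceptor)
    # background: internal GT/AG windows inside the intron
    b <- strsplit(iseq, "")[[1]]
    gt <- which(b[-L] == "G" & b[-1] == "T")
    gt <- gt[gt >= 6L & gt + 6L <= L & gt != 1L]
    ag <- which(b[-L] == "A" & b[-1] == "G")
    ag <- ag[ag >= 6L & ag + 6L <= L & ag != L - 1L]
    if (length(gt)) don_bg <- c(don_bg,
                                substring(iseq, gt - 5L, gt + 6L))
    if (length(ag)) acc_bg <- c(acc_bg,
                                substring(iseq, ag - 5L, ag + 6L))
  }
  if (!length(don_bg)) don_bg <- don_pos
  if (!length(acc_bg)) acc_bg <- acc_pos
  list(donor = build_ss_model(don_pos, don_bg, side = "5prime"),
       acceptor = build_ss_model(acc_pos, acc_bg, side = "3prime"))
}

#' Build the splicing-code feature matrix for one AS side
#'
#' One row per eligible exon-exon junction in genes carrying at least one
#' event of the given side: junctions with mean support below `min_reads`
#' or with more than one AS type are excluded; the label is `alternative`
#' for junctions carrying the side's AS type and `constitutive` otherwise.
#'
#' @param species_data list with `genome`, `genes`, `exons`, `junctions`.
#' @param events classified event table (all samples of the species).
#' @param side `"AltD"` or `"AltA"`.
#' @param models optional output of [build_species_ss_models()].
#' @param min_reads mean-support threshold (default 5).
#' @param all_genes use junctions of all genes rather than only AS genes.
#' @return data frame of features with a `label` factor column.
#' @export
build_feature_matrix <- function(species_data, events,
                                 side = c("AltD", "AltA"),
                                 models = NULL, min_reads = 5,
                                 all_genes = FALSE) {
  side <- match.arg(side)
  if (is.null(models)) models <- build_species_ss_models(species_data)
  model <- if (side == "AltD") models$donor else models$acceptor
  jall <- species_data$junctions
  n_samples <- length(unique(jall$sample_id))
  key <- paste(jall$chrom, jall$start, jall$end, jall$strand, sep = "\r")
  agg <- tapply(jall$reads, key, sum)
  jx <- jall[!duplicated(key), c("chrom", "start", "end", "strand")]
  jx$mean_reads <- as.numeric(agg[paste(jx$chrom, jx$start, jx$end,
                                        jx$strand, sep = "\r")]) / n_samples
  jx$gene_id <- .assign_genes(jx, species_data$genes)
  jx <- jx[!is.na(jx$gene_id) & jx$mean_reads >= min_reads, , drop = FALSE]
  types <- .junction_types(events, NULL)
  jx$jid <- sprintf("%s:%d-%d:%s", jx$chrom, jx$start, jx$end, jx$strand)
  n_types <- vapply(jx$jid, function(j) length(types[[j]] %||% character(0)),
                    integer(1))
  jx$type1 <- vapply(jx$jid, function(j) {
    t <- types[[j]] %||% character(0)
    if (length(t) == 1L) t else "none"
  }, "")
  jx <- jx[n_types <= 1L, , drop = FALSE]   # multi-type EEJs removed
  # the minor (alternative-site) junction of an AltD/AltA event is a
  # shadow of the authentic EEJ, not an independent junction: drop it
  minor_ids <- unique(sprintf(
    "%s:%d-%d:%s", events$chrom, events$incl_start, events$incl_end,
    events$strand)[events$type %in% c("AltD", "AltA")])
  jx <- jx[!(jx$jid %in% minor_ids), , drop = FALSE]
  # junctions carrying a different AS type are neither alternative (for
  # this side) nor constitutive: exclude them
  jx <- jx[jx$type1 %in% c("none", side), , drop = FALSE]
  if (!all_genes) {
    as_genes <- unique(jx$gene_id[jx$type1 == side])
    jx <- jx[jx$gene_id %in% as_genes, , drop = FALSE]
  }
  if (!nrow(jx)) return(NULL)
  rows <- lapply(seq_len(nrow(jx)), function(k) {
    iseq <- intron_sequence(species_data$genome, jx[k, ])
    d <- junction_distances(iseq, side = side, model = model)
    ppt <- find_tract(iseq, "polypyrimidine")
    ua <- find_tract(iseq, "UA")
    br <- find_branch_site(iseq)
    L <- nchar(iseq)
    w <- list(donor = substr(iseq, 1L, 7L),
              acceptor = substr(iseq, L - 6L, L))
    data.frame(
      junction_id = jx$jid[k], gene_id = jx$gene_id[k],
      label = factor(if (jx$type1[k] == side) "alternative"
                     else "constitutive",
                     levels = c("constitutive", "alternative")),
      junction_size = d$junction_size,
      has_alt_ss = as.integer(d$has_alt_ss),
      dist_alt_ss = if (d$has_alt_ss) d$dist_alt_ss else 150L,
      frame_alt_ss = as.integer(isTRUE(d$frame_alt_ss)),
      has_inter_gtag = as.integer(d$has_inter),
      dist_inter_gtag = if (d$has_inter) d$dist_inter else 150L,
      frame_inter_gtag = as.integer(isTRUE(d$frame_inter)),
      ppt_present = as.integer(!is.null(ppt)),
      ua_present = as.integer(!is.null(ua)),
      branch_present = as.integer(!is.null(br)),
      mean_reads = jx$mean_reads[k],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
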