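# Synthetic multi-species cohort generator.
#
# Genes are built as exon/intron mosaics with GT..AG introns on the sense
# strand, a designed ATG..stop open reading frame whose stop codon sits in
# the final exon, and splice-site consensus contexts written (with noise)
# around every authentic and planted alternative splice site.  AS events of
# the four types (IR, AltD, AltA, ES) are planted at known junctions with
# known PSI; junction read counts are sampled binomially; species are derived
# by i.i.d. substitution (codon-aware inside reading frames so no spurious
# stop codons arise); PTC-generating minor isoforms are engineered to satisfy
# the 50-nt rule with a verified margin.

# consensus written (with per-base noise) on the intron side of splice sites
.DONOR_CTX <- "AAGTT"     # intron positions 3..7, after the GT
.ACCEPTOR_CTX <- "TTGCA"  # the 5 intron bases just before the AG

#' Configuration for a synthetic multi-species splicing cohort
#'
#' All downstream analyses in the package can be exercised on cohorts drawn
#' from this configuration; the defaults describe a small plant-like world:
#' multi-exon genes with GT..AG introns, intron retention and alternative
#' acceptor as the dominant AS types, and mostly species-specific AS.
#'
#' @param n_genes number of genes per species.
#' @param exons_per_gene integer range `c(lo, hi)` of exons per gene.
#' @param exon_len,intron_len integer ranges (bp). Intron bounds must lie
#'   within the accepted mapping range `[41, 50000]`.
#' @param as_fraction fraction of junctions carrying a planted AS event.
#' @param as_type_mix named probabilities over `IR`, `AltD`, `AltA`, `ES`.
#' @param psi_range interval in (0,1) for planted event PSI.
#' @param depth mean supporting reads per junction.
#' @param n_species,n_tissues number of species and of tissue samples per
#'   species.
#' @param divergence per-site substitution probability between species.
#' @param conservation_mix named probabilities over `conserved`, `gained`,
#'   `lost` for planted events.
#' @param ptc_fraction fraction of AS events whose minor isoform is built to
#'   contain a premature termination codon.
#' @param determinant_signal strength (logit slope units) of the planted
#'   dependence of AS probability on the alternative splice-site distance;
#'   0 disables the signal.
#' @param tract_signal reduction of polypyrimidine-tract planting probability
#'   on AS junctions (0 disables).
#' @param psi_divergence,tissue_sd logit-scale standard deviations of the
#'   species-level PSI shift and of the residual per-sample noise.
#' @param tissue_effect_sd logit-scale standard deviation of a per-tissue
#'   PSI shift shared across species (0 disables; raise above
#'   `psi_divergence` to make profiles cluster by tissue instead of by
#'   species).
#' @param decoy_fraction fraction of constitutive junction rows emitted with
#'   a sub-threshold overhang (for filter tests).
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 200,
                          exons_per_gene = c(4L, 8L),
                          exon_len = c(80L, 200L),
                          intron_len = c(80L, 400L),
                          as_fraction = 0.15,
                          as_type_mix = c(IR = 0.40, AltD = 0.15,
                                          AltA = 0.30, ES = 0.15),
                          psi_range = c(0.1, 0.9),
                          depth = 50,
                          n_species = 2L,
                          n_tissues = 2L,
                          divergence = 0.02,
                          conservation_mix = c(conserved = 0.2,
                                               gained = 0.4, lost = 0.4),
                          ptc_fraction = 0.12,
                          determinant_signal = 0,
                          tract_signal = 0,
                          psi_divergence = 0.8,
                          tissue_sd = 0.2,
                          tissue_effect_sd = 0,
                          decoy_fraction = 0,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              as_fraction = as_fraction,
              as_type_mix = as_type_mix[c("IR", "AltD", "AltA", "ES")],
              psi_range = psi_range,
              depth = depth,
              n_species = as.integer(n_species),
              n_tissues = as.integer(n_tissues),
              divergence = divergence,
              conservation_mix =
                conservation_mix[c("conserved", "gained", "lost")],
              ptc_fraction = ptc_fraction,
              determinant_signal = determinant_signal,
              tract_signal = tract_signal,
              psi_divergence = psi_divergence,
              tissue_sd = tissue_sd,
              tissue_effect_sd = tissue_effect_sd,
              decoy_fraction = decoy_fraction,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  # alternative splice sites are planted >= 6 bp from the authentic site
  # and both junction isoforms must stay inside the accepted intron range,
  # so AS-carrying introns need at least 41 + 6 = 47 bp
  if (cfg$as_fraction > 0 && cfg$intron_len[1] < 47L)
    stopf(paste("infeasible geometry: intron_len lower bound %d cannot host",
                "the requested alternative splice-site distances",
                "(needs >= 47 bp)"), cfg$intron_len[1])
  if (cfg$intron_len[1] < 41L || cfg$intron_len[2] > 50000L)
    stopf("intron_len bounds must lie within [41, 50000], got [%d, %d]",
          cfg$intron_len[1], cfg$intron_len[2])
  for (nm in c("as_type_mix", "conservation_mix")) {
    p <- cfg[[nm]]
    if (anyNA(p) || abs(sum(p) - 1) > 1e-9)
      stopf("%s must be a complete probability vector summing to 1", nm)
  }
  if (cfg$psi_range[1] <= 0 || cfg$psi_range[2] >= 1 ||
      cfg$psi_range[1] > cfg$psi_range[2])
    stopf("psi_range must be an interval within (0, 1)")
  if (cfg$as_fraction < 0 || cfg$as_fraction > 1)
    stopf("as_fraction must be in [0, 1]")
  if (cfg$exon_len[1] < 60L)
    stopf("exon_len lower bound must be >= 60 bp (UTR + coding layout)")
  if (cfg$n_species < 1L || cfg$n_tissues < 1L)
    stopf("n_species and n_tissues must be >= 1")
  invisible(cfg)
}

# ---- internal ORF / PTC checker (independent of the ptc module) -----------

# Longest ATG-initiated forward ORF; returns c(start, end, length,
# has_stop) in 1-based mature coordinates, or NULL.  Vectorised scan of all
# codon windows; first in-frame stop after each ATG via position filtering.
.scan_longest_orf <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(NULL)
  b <- strsplit(seq, "")[[1]]
  atg <- which(b == "A")
  atg <- atg[atg + 2 <= n & b[atg + 1] == "T" & b[atg + 2] == "G"]
  if (!length(atg)) return(NULL)
  idx <- seq_len(n - 2L)
  cod <- paste0(b[idx], b[idx + 1L], b[idx + 2L])
  stops <- which(cod %in% STOP_CODONS)
  best <- NULL
  for (s in atg) {
    fs <- stops[stops >= s + 3L & (stops - s) %% 3L == 0L]
    if (length(fs)) {
      end <- fs[1] + 2L; len <- end - s + 1L; has <- 1L
    } else {
      len <- ((n - s + 1L) %/% 3L) * 3L; end <- s + len - 1L; has <- 0L
    }
    if (is.null(best) || len > best[3]) best <- c(s, end, len, has)
  }
  best
}

# 50-nt rule on a mature sequence with junction positions (position = number
# of bases 5' of the boundary).
.scan_has_ptc <- function(seq, junctions) {
  if (!length(junctions)) return(FALSE)
  orf <- .scan_longest_orf(seq)
  if (is.null(orf) || orf[4] == 0L) return(FALSE)
  (max(junctions) - orf[2]) >= 50L
}

# ---- gene construction ----------------------------------------------------

.sample_range <- function(rng, n) {
  if (rng[1] >= rng[2]) rep(rng[1], n) else sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

# overwrite `ctx` into string `x` at 1-based position, with per-base noise
.write_ctx <- function(x, pos, ctx, fidelity = 0.85) {
  cc <- strsplit(ctx, "")[[1]]
  keep <- runif(length(cc)) < fidelity
  cc[!keep] <- sample(DNA_BASES, sum(!keep), replace = TRUE)
  substr(x, pos, pos + length(cc) - 1L) <- paste(cc, collapse = "")
  x
}

# Plan one ancestral gene: exon/intron geometry, ORF layout, planted events.
# Event presence per species is decided here; sequence realisation is done
# per species in .realize_gene().
.plan_gene <- function(cfg, gene_idx) {
  n_ex <- .sample_range(cfg$exons_per_gene, 1L)
  ex_len <- .sample_range(cfg$exon_len, n_ex)
  n_in <- n_ex - 1L
  in_len <- if (n_in > 0) .sample_range(cfg$intron_len, n_in) else integer(0)

  # AS planting per intron
  events <- list()
  used <- rep(FALSE, max(n_in, 1L))
  if (n_in > 0 && cfg$as_fraction > 0) {
    # both isoforms of an AltD/AltA pair must respect the 41-bp minimum
    # intron length, and the alternative site needs 19 bp of context
    d_all <- sample(seq(6L, 60L, by = 3L), n_in, replace = TRUE)
    d_all <- pmin(d_all, in_len - 41L, in_len - 19L)
    d_all <- pmax(d_all, 6L)
    s <- cfg$determinant_signal
    p_as <- if (s > 0) {
      plogis(qlogis(cfg$as_fraction) + s * (33 - d_all) / 16)
    } else rep(cfg$as_fraction, n_in)
    for (i in seq_len(n_in)) {
      if (used[i] || runif(1) >= p_as[i]) next
      type <- sample(names(cfg$as_type_mix), 1L, prob = cfg$as_type_mix)
      if (type == "ES" && (i >= n_in || used[i + 1L])) {
        # ES infeasible here: fall back to another planned type so the
        # realised AS fraction stays binomial around as_fraction
        p_alt <- cfg$as_type_mix[setdiff(names(cfg$as_type_mix), "ES")]
        if (sum(p_alt) <= 0) next
        type <- sample(names(p_alt), 1L, prob = p_alt)
      }
      cons <- sample(names(cfg$conservation_mix), 1L,
                     prob = cfg$conservation_mix)
      ptc <- FALSE
      if (type != "ES" && i < n_in && runif(1) < cfg$ptc_fraction) ptc <- TRUE
      if (type == "IR") in_len[i] <- in_len[i] - (in_len[i] %% 3L)
      if (type == "ES") {
        used[i + 1L] <- TRUE
        ex_len[i + 1L] <- ex_len[i + 1L] - (ex_len[i + 1L] %% 3L)
      }
      used[i] <- TRUE
      events[[length(events) + 1L]] <-
        list(intron = i, type = type, d = d_all[i], ptc = ptc,
             conservation = cons,
             psi = runif(1, cfg$psi_range[1], cfg$psi_range[2]),
             tissue_delta = rnorm(cfg$n_tissues, 0, cfg$tissue_effect_sd))
    }
    d_planted <- d_all
  } else {
    d_planted <- if (n_in > 0) sample(seq(6L, 60L, by = 3L), n_in, replace = TRUE) else integer(0)
    d_planted <- if (n_in > 0)
      pmax(pmin(d_planted, in_len - 41L, in_len - 19L), 6L) else integer(0)
  }

  # ORF layout on the mature (sense, spliced) major isoform
  total_ex <- sum(ex_len)
  utr5 <- 24L
  utr3 <- 24L + (total_ex - 24L - 24L) %% 3L
  coding_len <- total_ex - utr5 - utr3
  list(idx = gene_idx, n_ex = n_ex, ex_len = ex_len, in_len = in_len,
       utr5 = utr5, utr3 = utr3, coding_len = coding_len,
       d_planted = d_planted, events = events,
       strand = sample(c("+", "-"), 1L),
       # per-gene expression level (lognormal, as in real transcriptomes)
       expr_mult = exp(rnorm(1L, 0, 0.7)),
       # per-intron regulatory planting (shared intent across species)
       tract_len = sample(9:14, max(n_in, 1L), replace = TRUE),
       tract_off = sample(0:6, max(n_in, 1L), replace = TRUE),
       branch_off = sample(20:32, max(n_in, 1L), replace = TRUE),
       branch_plant = runif(max(n_in, 1L)) < 0.7)
}

# Ancestral sequence parts for a planned gene: list(exons=character,
# introns=character) on the sense strand, with all consensus contexts,
# tracts, branch sites, alternative splice sites and PTC stops written.
.build_ancestral <- function(cfg, plan) {
  utr5 <- random_dna(plan$utr5)
  utr5 <- gsub("ATG", "ACG", utr5)
  utr3 <- random_dna(plan$utr3)
  utr3 <- gsub("ATG", "ACG", utr3)
  coding <- paste0("ATG", random_codons(plan$coding_len / 3L - 2L), "TAA")
  mature <- paste0(utr5, coding, utr3)
  cum <- cumsum(plan$ex_len)
  exons <- substring(mature, c(1L, head(cum, -1L) + 1L), cum)

  ev_by_intron <- list()
  for (ev in plan$events) ev_by_intron[[as.character(ev$intron)]] <- ev

  introns <- character(length(plan$in_len))
  tract_planted <- logical(length(plan$in_len))
  for (i in seq_along(plan$in_len)) {
    L <- plan$in_len[i]
    x <- paste0("GT", random_dna(L - 4L), "AG")
    x <- .write_ctx(x, 3L, .DONOR_CTX)
    x <- .write_ctx(x, L - 6L, .ACCEPTOR_CTX)
    if (plan$branch_plant[i] && L >= plan$branch_off[i] + 16L) {
      bstart <- L - 2L - plan$branch_off[i] - 6L
      if (bstart >= 9L) substr(x, bstart, bstart + 6L) <- "TACTAAC"
    }
    ev <- ev_by_intron[[as.character(i)]]
    is_as <- !is.null(ev)
    p_tr <- 0.8 - if (is_as) cfg$tract_signal else 0
    if (runif(1) < p_tr && L >= 30L) {
      tl <- min(plan$tract_len[i], L - 16L)
      tend <- L - 2L - plan$tract_off[i]
      substr(x, tend - tl + 1L, tend) <-
        paste(sample(c("C", "T"), tl, replace = TRUE), collapse = "")
      tract_planted[i] <- TRUE
    }
    introns[i] <- x
  }
  list(exons = exons, introns = introns, tract_planted = tract_planted)
}

# Codon-aware substitution: mutate whole codons to random non-stop codons
# with probability 1-(1-div)^3, skipping protected codon indices.
.diverge_codons <- function(x, div, protect_codon = integer(0)) {
  n <- floor(nchar(x) / 3L)
  if (n == 0L) return(x)
  hit <- which(runif(n) < 1 - (1 - div)^3)
  hit <- setdiff(hit, protect_codon)
  if (!length(hit)) return(x)
  all_codons <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0))
  ok <- setdiff(all_codons, STOP_CODONS)
  for (k in hit) substr(x, 3L * k - 2L, 3L * k) <- sample(ok, 1L)
  x
}

# Base-level substitution skipping protected 1-based positions.
.diverge_bases <- function(x, div, protect = integer(0)) {
  n <- nchar(x)
  hit <- setdiff(which(runif(n) < div), protect)
  if (!length(hit)) return(x)
  b <- strsplit(x, "")[[1]]
  for (p in hit) b[p] <- sample(setdiff(DNA_BASES, b[p]), 1L)
  paste(b, collapse = "")
}

# Insert segment (minor-isoform exonified sequence) for an event, given the
# realised intron string.  Returns 1-based [from, to] within the intron.
.insert_span <- function(ev, L) {
  switch(ev$type,
    AltD = c(1L, ev$d),
    AltA = c(L - ev$d + 1L, L),
    IR   = c(1L, L),
    ES   = NULL)
}

# Make the insert free of in-frame stop codons (given phase of the first
# insert base within the reading frame), optionally planting one stop.
# `protect` are intron-local positions that must not change.
.sanitize_insert <- function(intron, span, phase, plant_stop, protect) {
  ins_from <- span[1]; ins_to <- span[2]
  d <- ins_to - ins_from + 1L
  # codon slots fully inside the insert
  off0 <- (3L - phase) %% 3L           # 0-based offset of first full codon
  slots <- seq.int(off0, d - 3L, by = 3L)
  if (!length(slots) && plant_stop) return(NULL)
  all_codons <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0))
  okc <- setdiff(all_codons, STOP_CODONS)
  stop_slot <- NA_integer_
  if (plant_stop) {
    free <- slots[vapply(slots, function(o) {
      pos <- ins_from + o
      !any(seq(pos, pos + 2L) %in% protect)
    }, logical(1))]
    if (!length(free)) return(NULL)
    stop_slot <- free[1]
  }
  for (o in slots) {
    pos <- ins_from + o            # 1-based start of codon in intron
    cod <- substr(intron, pos, pos + 2L)
    if (!is.na(stop_slot) && o == stop_slot) {
      substr(intron, pos, pos + 2L) <- "TAA"
    } else if (cod %in% STOP_CODONS) {
      if (any(seq(pos, pos + 2L) %in% protect)) next
      substr(intron, pos, pos + 2L) <- sample(okc, 1L)
    }
  }
  list(intron = intron, stop_slot = stop_slot)
}

# Realise one species' copy of a gene: apply divergence, enforce planted
# structures, verify PTC intents.  Returns exon/intron strings plus event
# realisation details.
.realize_gene <- function(cfg, plan, anc, present, first_species) {
  div <- if (first_species) 0 else cfg$divergence
  ex_len <- plan$ex_len; in_len <- plan$in_len
  cum <- cumsum(ex_len)
  utr5 <- plan$utr5; coding_len <- plan$coding_len

  exons <- anc$exons
  if (div > 0) {
    mature <- paste(exons, collapse = "")
    cod <- substr(mature, utr5 + 1L, utr5 + coding_len)
    cod <- .diverge_codons(cod, div,
                           protect_codon = c(1L, coding_len / 3L))
    u5 <- .diverge_bases(substr(mature, 1L, utr5), div)
    u5 <- gsub("ATG", "ACG", u5)
    u3 <- .diverge_bases(substr(mature, utr5 + coding_len + 1L,
                                nchar(mature)), div)
    u3 <- gsub("ATG", "ACG", u3)
    mature <- paste0(u5, cod, u3)
    exons <- substring(mature, c(1L, head(cum, -1L) + 1L), cum)
  }

  ev_by_intron <- list()
  for (ev in plan$events) ev_by_intron[[as.character(ev$intron)]] <- ev

  introns <- anc$introns
  ev_real <- list()
  for (i in seq_along(introns)) {
    L <- in_len[i]
    x <- introns[i]
    ev <- ev_by_intron[[as.character(i)]]
    has_ev <- !is.null(ev) && isTRUE(present[as.character(i)])
    protect <- c(1:2, (L - 1L):L)
    if (has_ev && ev$type %in% c("AltD", "AltA")) {
      if (ev$type == "AltD") {
        protect <- c(protect, (ev$d + 1L):(ev$d + 7L))
      } else {
        protect <- c(protect, (L - ev$d - 6L):(L - ev$d))
      }
    }
    if (div > 0) x <- .diverge_bases(x, div, protect = protect)
    # enforce terminal dinucleotides and contexts
    substr(x, 1L, 2L) <- "GT"; substr(x, L - 1L, L) <- "AG"
    if (has_ev) {
      if (ev$type == "AltD") {
        substr(x, ev$d + 1L, ev$d + 2L) <- "GT"
        x <- .write_ctx(x, ev$d + 3L, .DONOR_CTX, fidelity = 0.95)
      } else if (ev$type == "AltA") {
        substr(x, L - ev$d - 1L, L - ev$d) <- "AG"
        x <- .write_ctx(x, L - ev$d - 6L, .ACCEPTOR_CTX, fidelity = 0.95)
      }
      span <- .insert_span(ev, L)
      if (!is.null(span)) {
        ins_pos0 <- cum[i]  # 0-based mature position of the insertion point
        phase <- (ins_pos0 - utr5) %% 3L
        res <- .sanitize_insert(x, span, phase, ev$ptc, protect)
        if (is.null(res)) { ev$ptc <- FALSE
          res <- .sanitize_insert(x, span, phase, FALSE, protect) }
        x <- res$intron
      }
    } else if (!is.null(ev) && ev$type %in% c("AltD", "AltA")) {
      # event lost/not yet gained here: destroy the alternative site
      if (ev$type == "AltD") {
        if (substr(x, ev$d + 1L, ev$d + 2L) == "GT")
          substr(x, ev$d + 1L, ev$d + 2L) <- "CC"
      } else {
        if (substr(x, L - ev$d - 1L, L - ev$d) == "AG")
          substr(x, L - ev$d - 1L, L - ev$d) <- "CC"
      }
    }
    introns[i] <- x
    if (has_ev) ev_real[[as.character(i)]] <- ev
  }

  # verify PTC intents on minor isoforms; record realised truth
  for (k in names(ev_real)) {
    ev <- ev_real[[k]]
    iso <- .minor_isoform(plan, exons, introns, ev)
    got <- .scan_has_ptc(iso$mature, iso$junctions)
    ev_real[[k]]$ptc <- got
  }
  list(exons = exons, introns = introns, events = ev_real)
}

# Minor-isoform mature sequence and mature-coordinate junction positions.
.minor_isoform <- function(plan, exons, introns, ev) {
  i <- ev$intron
  n_ex <- plan$n_ex
  L <- plan$in_len[i]
  if (ev$type == "ES") {
    segs <- exons[setdiff(seq_len(n_ex), i + 1L)]
    mature <- paste(segs, collapse = "")
    juncs <- cumsum(nchar(segs))
    juncs <- juncs[-length(juncs)]
    return(list(mature = mature, junctions = juncs))
  }
  span <- .insert_span(ev, L)
  insert <- substr(introns[i], span[1], span[2])
  if (ev$type == "IR") {
    segs <- c(exons[seq_len(i - 1L)],
              paste0(exons[i], insert, exons[i + 1L]),
              if (i + 2L <= n_ex) exons[(i + 2L):n_ex])
  } else if (ev$type == "AltD") {
    segs <- c(exons[seq_len(i - 1L)], paste0(exons[i], insert),
              exons[(i + 1L):n_ex])
  } else {  # AltA
    segs <- c(exons[seq_len(i)], paste0(insert, exons[i + 1L]),
              if (i + 2L <= n_ex) exons[(i + 2L):n_ex])
  }
  mature <- paste(segs, collapse = "")
  juncs <- cumsum(nchar(segs))
  juncs <- juncs[-length(juncs)]
  list(mature = mature, junctions = juncs)
}

# genomic (0-based half-open) interval of sense-coordinate [a0, b0) within a
# gene placed at offset g0 with total length Lg on `strand`
.sense_to_genomic <- function(a0, b0, g0, Lg, strand) {
  if (strand == "+") c(g0 + a0, g0 + b0) else c(g0 + Lg - b0, g0 + Lg - a0)
}

#' Generate a synthetic multi-species cohort
#'
#' Deterministic given the config seed.  Returns genomes, gene models,
#' per-sample junction tables with sampled read support, isoform transcript
#' models for planted events, protein sets, an ortholog map and a ground
#' truth table.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  with_seed(derive_seed(config$seed, 101L), .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  species_names <- paste0("sp", seq_len(cfg$n_species))
  plans <- lapply(seq_len(cfg$n_genes), function(g) .plan_gene(cfg, g))
  ancestral <- lapply(plans, function(p) .build_ancestral(cfg, p))

  # species presence per event (relative to species 1)
  presence <- lapply(seq_along(plans), function(g) {
    evs <- plans[[g]]$events
    pres <- list()
    for (ev in evs) {
      pr <- switch(ev$conservation,
        conserved = rep(TRUE, cfg$n_species),
        lost = c(TRUE, rep(FALSE, cfg$n_species - 1L)),
        gained = if (cfg$n_species == 1L) TRUE else
          c(FALSE, rep(TRUE, cfg$n_species - 1L)))
      pres[[as.character(ev$intron)]] <- pr
    }
    pres
  })

  spacer <- 100L
  species <- list()
  truth_events <- list()
  truth_junctions <- list()
  truth_psi <- list()

  for (si in seq_len(cfg$n_species)) {
    sp <- species_names[si]
    offset <- 0L
    genome_parts <- character(0)
    gene_rows <- exon_rows <- tx_rows <- list()
    jx_template <- list()   # per-gene junction geometry
    proteins <- character(0)

    for (g in seq_along(plans)) {
      plan <- plans[[g]]
      pres_g <- vapply(presence[[g]], function(p) p[si], logical(1))
      real <- .realize_gene(cfg, plan, ancestral[[g]],
                            present = pres_g, first_species = (si == 1L))
      gene_id <- sprintf("%s_g%03d", sp, g)
      # event ids and the species-level PSI draw (one per event per species)
      for (i in names(real$events)) {
        ev <- real$events[[i]]
        ev$event_id <- sprintf("g%03d_i%s_%s", g, i, ev$type)
        ev$psi_sp <- if (si == 1L) ev$psi else
          plogis(qlogis(ev$psi) + rnorm(1L, 0, cfg$psi_divergence))
        real$events[[i]] <- ev
      }
      n_ex <- plan$n_ex
      sense <- character(0)
      for (i in seq_len(n_ex)) {
        sense <- c(sense, real$exons[i])
        if (i < n_ex) sense <- c(sense, real$introns[i])
      }
      sense_seq <- paste(sense, collapse = "")
      Lg <- nchar(sense_seq)
      g0 <- offset + spacer
      strand <- plan$strand
      genome_parts <- c(genome_parts, random_dna(spacer),
                        if (strand == "+") sense_seq else revcomp(sense_seq))
      offset <- g0 + Lg

      # sense coordinates of exons and introns (0-based half-open)
      ex_start <- integer(n_ex); ex_end <- integer(n_ex)
      in_start <- integer(max(n_ex - 1L, 0L)); in_end <- in_start
      pos <- 0L
      for (i in seq_len(n_ex)) {
        ex_start[i] <- pos; pos <- pos + plan$ex_len[i]; ex_end[i] <- pos
        if (i < n_ex) {
          in_start[i] <- pos; pos <- pos + plan$in_len[i]; in_end[i] <- pos
        }
      }
      gene_rows[[g]] <- data.frame(
        gene_id = gene_id, chrom = "chr1", start = g0, end = g0 + Lg,
        strand = strand, stringsAsFactors = FALSE)
      exon_rows[[g]] <- do.call(rbind, lapply(seq_len(n_ex), function(i) {
        gc <- .sense_to_genomic(ex_start[i], ex_end[i], g0, Lg, strand)
        data.frame(gene_id = gene_id, exon_rank = i, chrom = "chr1",
                   start = gc[1], end = gc[2], strand = strand,
                   stringsAsFactors = FALSE)
      }))

      # protein
      mature <- paste(real$exons, collapse = "")
      cod <- substr(mature, plan$utr5 + 1L, plan$utr5 + plan$coding_len)
      proteins[gene_id] <- sub("\\*$", "", translate_nt(cod))

      # major transcript
      blocks_major <- lapply(seq_len(n_ex), function(i)
        .sense_to_genomic(ex_start[i], ex_end[i], g0, Lg, strand))
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
        event_id = NA_character_, role = "major",
        blocks = .encode_blocks(blocks_major), strand = strand,
        stringsAsFactors = FALSE)

      # junction geometry (authentic introns + event alternatives)
      jx_g <- list()
      for (i in seq_len(max(n_ex - 1L, 0L))) {
        gc <- .sense_to_genomic(in_start[i], in_end[i], g0, Lg, strand)
        ev <- real$events[[as.character(i)]]
        alt_gc <- NULL
        if (!is.null(ev)) {
          alt <- .alt_junction_sense(plan, ev, in_start, in_end)
          alt_gc <- .sense_to_genomic(alt[1], alt[2], g0, Lg, strand)
        }
        jx_g[[i]] <- list(gene_id = gene_id, intron = i,
                          start = gc[1], end = gc[2], strand = strand,
                          sense_start = in_start[i], sense_end = in_end[i],
                          g0 = g0, Lg = Lg, expr_mult = plan$expr_mult,
                          event = ev, alt = alt_gc, es_partner = FALSE)
        truth_junctions[[length(truth_junctions) + 1L]] <- data.frame(
          species = sp, gene_id = gene_id, intron_index = i,
          chrom = "chr1", start = gc[1], end = gc[2], strand = strand,
          alt_d = plan$d_planted[i],
          is_as = !is.null(ev),
          as_type = if (!is.null(ev)) ev$type else "none",
          tract_planted = ancestral[[g]]$tract_planted[i],
          stringsAsFactors = FALSE)
      }
      # an intron that provides the second inclusion junction of a present
      # ES event must not also emit constitutive reads
      for (i in seq_along(jx_g)) {
        ev <- jx_g[[i]]$event
        if (!is.null(ev) && ev$type == "ES") jx_g[[i + 1L]]$es_partner <- TRUE
      }
      jx_template[[gene_id]] <- jx_g

      # events: truth + minor transcripts
      for (i in names(real$events)) {
        ev <- real$events[[i]]
        ii <- as.integer(i)
        event_id <- ev$event_id
        alt_gc <- jx_g[[ii]]$alt
        truth_events[[length(truth_events) + 1L]] <- data.frame(
          event_id = event_id, species = sp, gene_id = gene_id,
          intron_index = ii, type = ev$type, true_psi = ev$psi,
          species_psi = ev$psi_sp,
          ptc_planted = ev$ptc, conservation = ev$conservation,
          alt_d = ev$d, chrom = "chr1",
          start = jx_g[[ii]]$start, end = jx_g[[ii]]$end,
          alt_start = alt_gc[1], alt_end = alt_gc[2],
          strand = strand, stringsAsFactors = FALSE)
        blocks_minor <- .minor_blocks(plan, ev, ex_start, ex_end,
                                      in_start, in_end, g0, Lg, strand)
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          transcript_id = paste0(gene_id, ".", event_id, ".maj"),
          gene_id = gene_id, event_id = event_id, role = "event_major",
          blocks = .encode_blocks(blocks_major), strand = strand,
          stringsAsFactors = FALSE)
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          transcript_id = paste0(gene_id, ".", event_id, ".min"),
          gene_id = gene_id, event_id = event_id, role = "event_minor",
          blocks = .encode_blocks(blocks_minor), strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    genome <- paste(c(genome_parts, random_dna(spacer)), collapse = "")

    # per-sample junction read tables
    jx_rows <- list()
    for (ti in seq_len(cfg$n_tissues)) {
      sample_id <- sprintf("%s_t%d", sp, ti)
      for (gene_id in names(jx_template)) {
        for (jx in jx_template[[gene_id]]) {
          if (isTRUE(jx$es_partner)) next
          ev <- jx$event
          depth_g <- cfg$depth * jx$expr_mult
          if (is.null(ev)) {
            reads <- rpois(1L, depth_g)
            if (reads > 0) {
              oh <- if (cfg$decoy_fraction > 0 &&
                        runif(1) < cfg$decoy_fraction) 10L else 25L
              jx_rows[[length(jx_rows) + 1L]] <- data.frame(
                chrom = "chr1", start = jx$start, end = jx$end,
                strand = jx$strand, reads = reads, min_overhang = oh,
                intron_coverage = 0L, sample_id = sample_id,
                stringsAsFactors = FALSE)
            }
            next
          }
          psi_st <- plogis(qlogis(ev$psi_sp) + ev$tissue_delta[ti] +
                           rnorm(1L, 0, cfg$tissue_sd))
          counts <- emit_junction_counts(psi_st, depth_g)
          incl <- counts[["inclusion"]]; excl <- counts[["exclusion"]]
          total <- incl + excl
          truth_psi[[length(truth_psi) + 1L]] <- data.frame(
            event_id = ev$event_id, species = sp, sample_id = sample_id,
            true_psi = psi_st, total_reads = total,
            stringsAsFactors = FALSE)
          alt_gc <- jx$alt
          add_row <- function(s, e, reads, cov = 0L) {
            if (reads <= 0 && cov <= 0) return()
            jx_rows[[length(jx_rows) + 1L]] <<- data.frame(
              chrom = "chr1", start = s, end = e, strand = jx$strand,
              reads = max(reads, 0L), min_overhang = 25L,
              intron_coverage = cov, sample_id = sample_id,
              stringsAsFactors = FALSE)
          }
          if (ev$type == "IR") {
            add_row(jx$start, jx$end, excl, cov = incl)
          } else if (ev$type %in% c("AltD", "AltA")) {
            add_row(jx$start, jx$end, excl)
            add_row(alt_gc[1], alt_gc[2], incl)
          } else {  # ES: inclusion split over the two flanking introns
            jx2 <- jx_template[[gene_id]][[jx$intron + 1L]]
            j1 <- incl %/% 2L; j2 <- incl - j1
            add_row(jx$start, jx$end, j1)
            add_row(jx2$start, jx2$end, j2)
            add_row(min(jx$start, jx2$start), max(jx$end, jx2$end), excl)
          }
        }
      }
    }
    junctions <- if (length(jx_rows)) do.call(rbind, jx_rows) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), reads = integer(0),
                 min_overhang = integer(0), intron_coverage = integer(0),
                 sample_id = character(0))
    species[[sp]] <- list(
      genome = c(chr1 = genome),
      genes = do.call(rbind, gene_rows),
      exons = do.call(rbind, exon_rows),
      transcripts = do.call(rbind, tx_rows),
      junctions = junctions,
      proteins = proteins)
  }

  ortholog_map <- NULL
  if (cfg$n_species >= 2L) {
    pairs <- utils::combn(species_names, 2L)
    ortholog_map <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      data.frame(species_a = pairs[1, k], species_b = pairs[2, k],
                 gene_a = sprintf("%s_g%03d", pairs[1, k],
                                  seq_len(cfg$n_genes)),
                 gene_b = sprintf("%s_g%03d", pairs[2, k],
                                  seq_len(cfg$n_genes)),
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(
    config = cfg,
    species = species,
    ortholog_map = ortholog_map,
    truth = list(
      events = if (length(truth_events)) do.call(rbind, truth_events) else NULL,
      junctions = if (length(truth_junctions))
        do.call(rbind, truth_junctions) else NULL,
      psi = if (length(truth_psi)) do.call(rbind, truth_psi) else NULL)),
    class = "synthetic_cohort")
}

#' Sample junction read counts for a planted event
#'
#' The inverse of the PSI formula: the total is drawn around `depth`
#' (Poisson, floored at 1) and the inclusion count is binomial with
#' success probability `true_psi`.  Uses the caller's RNG stream.
#'
#' @param true_psi true inclusion fraction in `[0, 1]`.
#' @param depth mean total supporting reads (> 0).
#' @return named integer vector `c(inclusion, exclusion)`.
#' @export
emit_junction_counts <- function(true_psi, depth) {
  if (is.na(true_psi) || true_psi < 0 || true_psi > 1)
    stopf("true_psi must be in [0, 1]")
  if (!is.finite(depth) || depth <= 0) stopf("depth must be > 0")
  total <- max(rpois(1L, depth), 1L)
  incl <- rbinom(1L, total, true_psi)
  c(inclusion = incl, exclusion = total - incl)
}

# alternative junction interval in sense coordinates (0-based half-open)
.alt_junction_sense <- function(plan, ev, in_start, in_end) {
  i <- ev$intron
  switch(ev$type,
    AltD = c(in_start[i] + ev$d, in_end[i]),
    AltA = c(in_start[i], in_end[i] - ev$d),
    IR   = c(in_start[i], in_end[i]),
    ES   = c(in_start[i], in_end[i + 1L]))
}

.minor_blocks <- function(plan, ev, ex_start, ex_end, in_start, in_end,
                          g0, Lg, strand) {
  i <- ev$intron; n_ex <- plan$n_ex
  sense_blocks <- switch(ev$type,
    AltD = {
      b <- Map(c, ex_start, ex_end)
      b[[i]] <- c(ex_start[i], ex_end[i] + ev$d); b
    },
    AltA = {
      b <- Map(c, ex_start, ex_end)
      b[[i + 1L]] <- c(ex_start[i + 1L] - ev$d, ex_end[i + 1L]); b
    },
    IR = {
      b <- Map(c, ex_start, ex_end)
      b[[i]] <- c(ex_start[i], ex_end[i + 1L])
      b[-(i + 1L)]
    },
    ES = Map(c, ex_start, ex_end)[-(i + 1L)])
  lapply(sense_blocks, function(ab)
    .sense_to_genomic(ab[1], ab[2], g0, Lg, strand))
}

.encode_blocks <- function(blocks) {
  blocks <- blocks[order(vapply(blocks, `[[`, 0, 1L))]
  paste(vapply(blocks, function(b) paste0(b[1], "-", b[2]), ""),
        collapse = ";")
}

.decode_blocks <- function(x) {
  lapply(strsplit(strsplit(x, ";")[[1]], "-"),
         function(p) as.integer(p))
}
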