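# Bundle writer/reader for synthetic cohorts: FASTA genomes and proteomes,
# GFF3 gene/transcript models, TSV junction tables and ground truth.
# Coordinates are 0-based half-open in memory and 1-based inclusive in GFF3.

JUNCTION_COLS <- c("chrom", "start", "end", "strand", "reads",
                   "min_overhang", "intron_coverage", "sample_id")

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits, per species: genome FASTA, protein FASTA, GFF3 gene/transcript
#' models and a TSV junction table; plus cohort-level ground-truth TSVs, the
#' ortholog map and the configuration as JSON.  The bundle round-trips
#' losslessly through [read_bundle()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of written file paths.
#' @export
write_bundle <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory: %s", out_dir)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }

  for (sp in names(cohort$species)) {
    spd <- cohort$species[[sp]]
    genome <- Biostrings::DNAStringSet(spd$genome)
    Biostrings::writeXStringSet(
      genome, emit(file.path(out_dir, sprintf("genome_%s.fa", sp))))
    prot <- Biostrings::AAStringSet(spd$proteins)
    Biostrings::writeXStringSet(
      prot, emit(file.path(out_dir, sprintf("proteins_%s.fa", sp))))
    .write_models_gff3(
      spd, emit(file.path(out_dir, sprintf("genes_%s.gff3", sp))))
    utils::write.table(
      spd$junctions[, JUNCTION_COLS],
      emit(file.path(out_dir, sprintf("junctions_%s.tsv", sp))),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in c("events", "junctions", "psi")) {
    df <- cohort$truth[[nm]]
    path <- emit(file.path(out_dir, sprintf("truth_%s.tsv", nm)))
    if (is.null(df)) {
      hdr <- switch(nm,
        events = c("event_id", "species", "gene_id", "intron_index", "type",
                   "true_psi", "species_psi", "ptc_planted", "conservation",
                   "alt_d", "chrom", "start", "end", "alt_start", "alt_end",
                   "strand"),
        junctions = c("species", "gene_id", "intron_index", "chrom", "start",
                      "end", "strand", "alt_d", "is_as", "as_type",
                      "tract_planted"),
        psi = c("event_id", "species", "sample_id", "true_psi",
                "total_reads"))
      writeLines(paste(hdr, collapse = "\t"), path)
    } else {
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  if (!is.null(cohort$ortholog_map)) {
    utils::write.table(cohort$ortholog_map,
                       emit(file.path(out_dir, "ortholog_map.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- unclass(cohort$config)
  # named vectors must serialise as JSON objects to keep their names
  cfg <- lapply(cfg, function(x) if (!is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(cfg, emit(file.path(out_dir, "config.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(written)
}

.write_models_gff3 <- function(spd, path) {
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  g <- spd$genes
  if (!is.null(g) && nrow(g)) {
    add(data.frame(chrom = g$chrom, source = "splicevol", type = "gene",
                   start = g$start + 1L, end = g$end, strand = g$strand,
                   attr = sprintf("ID=%s", g$gene_id),
                   stringsAsFactors = FALSE))
  }
  tx <- spd$transcripts
  if (!is.null(tx) && nrow(tx)) {
    for (k in seq_len(nrow(tx))) {
      blocks <- .decode_blocks(tx$blocks[k])
      lo <- min(vapply(blocks, `[[`, 0L, 1L))
      hi <- max(vapply(blocks, `[[`, 0L, 2L))
      ev <- if (is.na(tx$event_id[k])) "" else
        sprintf(";event_id=%s;role=%s", tx$event_id[k], tx$role[k])
      chrom <- spd$genes$chrom[match(tx$gene_id[k], spd$genes$gene_id)]
      add(data.frame(chrom = chrom, source = "splicevol", type = "mRNA",
                     start = lo + 1L, end = hi, strand = tx$strand[k],
                     attr = sprintf("ID=%s;Parent=%s%s", tx$transcript_id[k],
                                    tx$gene_id[k], ev),
                     stringsAsFactors = FALSE))
      for (b in blocks) {
        add(data.frame(chrom = chrom, source = "splicevol", type = "exon",
                       start = b[1] + 1L, end = b[2], strand = tx$strand[k],
                       attr = sprintf("Parent=%s", tx$transcript_id[k]),
                       stringsAsFactors = FALSE))
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), source = character(0),
               type = character(0), start = integer(0), end = integer(0),
               strand = character(0), attr = character(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df)) {
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       df$chrom, df$source, df$type, df$start, df$end,
                       df$strand, df$attr), con)
  }
}

#' Read gene and transcript models from GFF3
#'
#' Parses a GFF3 file (as written by [write_bundle()], or any file with
#' gene/mRNA/exon features and ID/Parent attributes) into the gene table,
#' per-gene exon table (of the primary transcript) and transcript block
#' table used by the package.  Coordinates are converted to 0-based
#' half-open.
#'
#' @param path GFF3 file.
#' @return list with `genes`, `exons`, `transcripts` data frames.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, "")
  genes <- df[df$type == "gene", ]
  genes_df <- data.frame(gene_id = genes$ID, chrom = as.character(genes$seqnames),
                         start = genes$start - 1L, end = genes$end,
                         strand = as.character(genes$strand),
                         stringsAsFactors = FALSE)
  mrna <- df[df$type == "mRNA", ]
  ex <- df[df$type == "exon", ]
  tx_rows <- lapply(seq_len(nrow(mrna)), function(k) {
    tid <- mrna$ID[k]
    exk <- ex[ex$Parent == tid, , drop = FALSE]
    exk <- exk[order(exk$start), , drop = FALSE]
    blocks <- Map(c, exk$start - 1L, exk$end)
    data.frame(transcript_id = tid, gene_id = mrna$Parent[k],
               event_id = if ("event_id" %in% names(mrna))
                 mrna$event_id[k] else NA_character_,
               role = if ("role" %in% names(mrna) &&
                          !is.na(mrna$role[k])) mrna$role[k] else "major",
               blocks = .encode_blocks(blocks),
               strand = as.character(mrna$strand[k]),
               stringsAsFactors = FALSE)
  })
  transcripts <- if (length(tx_rows)) do.call(rbind, tx_rows) else NULL
  exon_rows <- NULL
  if (!is.null(transcripts)) {
    prim <- transcripts[transcripts$role == "major", , drop = FALSE]
    exon_rows <- do.call(rbind, lapply(seq_len(nrow(prim)), function(k) {
      blocks <- .decode_blocks(prim$blocks[k])
      strand <- prim$strand[k]
      ord <- if (strand == "-") rev(seq_along(blocks)) else seq_along(blocks)
      do.call(rbind, lapply(seq_along(blocks), function(j) {
        b <- blocks[[ord[j]]]
        data.frame(gene_id = prim$gene_id[k], exon_rank = j,
                   chrom = genes_df$chrom[match(prim$gene_id[k],
                                                genes_df$gene_id)],
                   start = b[1], end = b[2], strand = strand,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  list(genes = genes_df, exons = exon_rows, transcripts = transcripts)
}

#' Read a cohort bundle written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return a `synthetic_cohort`.
#' @export
read_bundle <- function(dir) {
  if (!dir.exists(dir)) stopf("bundle directory does not exist: %s", dir)
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfgl <- lapply(cfgl, function(x) if (is.list(x)) unlist(x) else x)
  cfg <- do.call(cohort_config, cfgl)
  sp_files <- list.files(dir, pattern = "^genome_.*\\.fa$")
  species_names <- sub("^genome_(.*)\\.fa$", "\\1", sp_files)
  species <- list()
  for (sp in species_names) {
    genome <- Biostrings::readDNAStringSet(
      file.path(dir, sprintf("genome_%s.fa", sp)))
    gseq <- setNames(as.character(genome),
                     sub("\\s.*", "", names(genome)))
    prot <- Biostrings::readAAStringSet(
      file.path(dir, sprintf("proteins_%s.fa", sp)))
    models <- read_gene_models(file.path(dir, sprintf("genes_%s.gff3", sp)))
    jx <- utils::read.delim(file.path(dir, sprintf("junctions_%s.tsv", sp)),
                            stringsAsFactors = FALSE)
    species[[sp]] <- list(genome = gseq, genes = models$genes,
                          exons = models$exons,
                          transcripts = models$transcripts,
                          junctions = jx,
                          proteins = setNames(as.character(prot),
                                              sub("\\s.*", "", names(prot))))
  }
  read_truth <- function(nm) {
    df <- utils::read.delim(file.path(dir, sprintf("truth_%s.tsv", nm)),
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0) NULL else df
  }
  om_path <- file.path(dir, "ortholog_map.tsv")
  structure(list(
    config = cfg,
    species = species,
    ortholog_map = if (file.exists(om_path))
      utils::read.delim(om_path, stringsAsFactors = FALSE) else NULL,
    truth = list(events = read_truth("events"),
                 junctions = read_truth("junctions"),
                 psi = read_truth("psi"))),
    class = "synthetic_cohort")
}
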