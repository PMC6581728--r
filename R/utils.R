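#' @import methods
#' @importFrom stats rbinom rpois rnorm runif quantile qlogis plogis
#'   phyper p.adjust fisher.test cor setNames complete.cases qbinom
#'   hclust as.dist cutree sd
#' @importFrom utils read.delim write.table head tail
NULL

# Run code with a private, restored RNG state. All seeded determinism in the
# package goes through this so callers' RNG streams are never disturbed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-local seed from a global one by a fixed offset, kept inside
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 31L + offset) %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

.GENETIC_CODE <- NULL
.genetic_code <- function() {
  if (is.null(.GENETIC_CODE)) {
    gc <- Biostrings::GENETIC_CODE
    utils::assignInMyNamespace(".GENETIC_CODE", gc)
  }
  .GENETIC_CODE
}

# Translate a nucleotide string in frame 1; trailing partial codon dropped;
# codons containing N translate to X.
translate_nt <- function(x) {
  n <- floor(nchar(x) / 3) * 3
  if (n < 3) return("")
  starts <- seq(1L, n, by = 3L)
  cods <- substring(x, starts, starts + 2L)
  aa <- .genetic_code()[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# n random codons avoiding stop codons (for building open reading frames).
random_codons <- function(n) {
  if (n == 0) return("")
  all_codons <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0))
  ok <- setdiff(all_codons, STOP_CODONS)
  paste(sample(ok, n, replace = TRUE), collapse = "")
}

# Karlin-Altschul style significance proxy for gapped BLOSUM62 local
# alignments: E = K * m * n * exp(-lambda * S). Standard gapped constants.
ka_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * as.double(m) * as.double(n) * exp(-lambda * score)
}

# IUPAC degenerate match of a pattern (e.g. "NNYTRAY") against equal-length
# string; returns TRUE/FALSE.
iupac_match <- function(pattern, x) {
  map <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), N = c("A", "C", "G", "T"))
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(x, "")[[1]]
  if (length(p) != length(s)) return(FALSE)
  all(vapply(seq_along(p), function(i) s[i] %in% map[[p[i]]], logical(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
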