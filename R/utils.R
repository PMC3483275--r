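#' @importFrom stats pnorm pbeta rexp rpois runif sd setNames var
#' @importFrom utils read.table write.table head combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic entry points route
# through this so that a seed argument fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  expr
}

# Deterministic sub-stream seed derivation: one master seed, one stream per
# unit (individual, bootstrap replicate, ...). Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

seq_to_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste(x, collapse = "")

# Alignment (named character vector of equal-length strings) -> character
# matrix, sequences in rows.
alignment_matrix <- function(seqs) {
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must be aligned to equal length (got lengths ",
         paste(unique(lens), collapse = ", "), ")")
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs)) else names(seqs)
  m
}

split_codons <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a nucleotide sequence in a fixed reading frame
#'
#' Standard genetic code; any trailing partial codon is dropped. Codons
#' containing non-ACGT characters translate to `"X"`.
#'
#' @param seq Nucleotide string.
#' @param frame Reading-frame offset in `0:2` (bases skipped before the
#'   first codon).
#' @return Amino-acid string; stop codons are `"*"`.
#' @export
translate_frame <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  seq <- toupper(seq)
  body <- substring(seq, frame + 1L, nchar(seq))
  n_codon <- nchar(body) %/% 3L
  if (n_codon < 1L) stop("sequence shorter than one codon in frame ", frame)
  codons <- split_codons(substring(body, 1L, n_codon * 3L))
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Copy of the standard genetic code, taken from Biostrings at load time so
# translation needs no XString round trip.
GENETIC_CODE_TABLE <- NULL

.onLoad <- function(libname, pkgname) {
  gc <- Biostrings::GENETIC_CODE
  utils::assignInMyNamespace("GENETIC_CODE_TABLE", setNames(as.character(gc), names(gc)))
  invisible()
}
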