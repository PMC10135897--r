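#' @importFrom data.table fread
#' @importFrom stats approx median pnorm quantile rnorm runif rpois setNames
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#' @param x character scalar over A/C/G/T/N
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Translate one codon, tolerating N ambiguity
#'
#' Codons containing N are resolved by enumerating all substitutions: if every
#' substitution yields the same amino acid, that residue is returned; otherwise
#' (including any mixture involving a stop) `NA` is returned, which callers
#' treat as "terminate without a stop codon".
#'
#' @param codon character vector of length 3 (single characters) or a
#'   3-character string
#' @return single amino-acid character, `"*"` for a stop, or `NA`
#' @keywords internal
translate_codon <- function(codon) {
  if (length(codon) == 1L) codon <- chars(codon)
  stopifnot(length(codon) == 3L)
  gc <- Biostrings::GENETIC_CODE
  if (!any(codon == "N")) {
    aa <- unname(gc[paste(codon, collapse = "")])
    if (is.na(aa)) stop("invalid codon: ", paste(codon, collapse = ""))
    return(aa)
  }
  opts <- lapply(codon, function(b) if (b == "N") c("A", "C", "G", "T") else b)
  combos <- expand.grid(opts, stringsAsFactors = FALSE)
  aas <- unique(unname(gc[apply(combos, 1L, paste, collapse = "")]))
  if (length(aas) == 1L && aas != "*") aas else NA_character_
}

# Validate a nucleotide string over the A/C/G/T/N alphabet.
check_nt <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string")
  if (grepl("[^ACGTN]", seq))
    stop(what, " contains characters outside A/C/G/T/N")
  invisible(seq)
}

# Fetch a named substitution matrix shipped with Biostrings (e.g. BLOSUM62),
# or pass a numeric matrix through unchanged.
get_submatrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

# Deterministic TSV writer: never quotes, never writes row names.
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  data.table = FALSE, ...))
}
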