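#' ORF-calling parameters
#'
#' @param min_orf_aa minimum reported protein length in amino acids. Default 50,
#'   the conventional lower bound for a credible micropeptide-sized product.
#' @param cycle_cap maximum number of full circle traversals a single
#'   translation event may use. A circle whose length is not divisible by 3
#'   returns to its starting codon phase after at most 3 traversals, so 3
#'   cycles provably exhaust all distinct codon phases; a frame that is still
#'   stop-free after that is rolling-circle by definition.
#' @param genetic_code genetic code id; only `"standard"` is supported.
#' @return an `orf_params` list
#' @export
orf_params <- function(min_orf_aa = 50L, cycle_cap = 3L,
                       genetic_code = "standard") {
  stopifnot(min_orf_aa >= 1L, cycle_cap >= 1L)
  if (!identical(genetic_code, "standard"))
    stop("only the standard genetic code is supported")
  structure(list(min_orf_aa = as.integer(min_orf_aa),
                 cycle_cap = as.integer(cycle_cap),
                 genetic_code = genetic_code),
            class = "orf_params")
}

#' Enumerate open reading frames on a circular sequence
#'
#' Treats `seq` as a covalently closed circle: every exact ATG is a candidate
#' start, and translation proceeds codon by codon around the circle (positions
#' taken modulo the circle length) until the first in-frame stop codon or until
#' `cycle_cap` full traversals have been consumed. ORFs that read through
#' position `L-1 -> 0` are flagged as junction-crossing. Frames that never hit
#' a stop within the cap are reported as rolling-circle, with the protein
#' truncated at the cap.
#'
#' Codons containing N never start an ORF and never count as stops; an N codon
#' whose translation is ambiguous terminates extension without a stop and the
#' candidate is dropped (conservative behaviour on dirty input).
#'
#' @param seq circular nucleotide sequence (single string, A/C/G/T/N)
#' @param params an [orf_params()] object
#' @return data.frame with one row per reported ORF: `start_nt` (0-based
#'   offset), `frame` (start modulo 3), `protein`, `length_aa`,
#'   `crosses_junction`, `cycles` (full traversals consumed, by ceiling),
#'   `rolling_circle`
#' @export
enumerate_circorfs <- function(seq, params = orf_params()) {
  check_nt(seq, "circular sequence")
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 3L) stop("circular sequence must be at least 3 nt long")
  cc <- chars(seq)
  max_codons <- (params$cycle_cap * L) %/% 3L

  rows <- vector("list", 0L)
  for (p in 0:(L - 1L)) {
    start_codon <- cc[(p + 0:2) %% L + 1L]
    if (!identical(paste(start_codon, collapse = ""), "ATG")) next
    aa <- character(max_codons)
    n_aa <- 0L
    stopped <- FALSE
    ambiguous <- FALSE
    nt_read <- 0L
    for (k in seq_len(max_codons) - 1L) {
      codon <- cc[(p + 3L * k + 0:2) %% L + 1L]
      res <- translate_codon(codon)
      if (is.na(res)) { ambiguous <- TRUE; break }
      if (res == "*") { stopped <- TRUE; nt_read <- 3L * (k + 1L); break }
      n_aa <- n_aa + 1L
      aa[n_aa] <- res
    }
    if (ambiguous) next                      # extension ended without a stop
    if (!stopped) nt_read <- 3L * max_codons # rolling-circle truncation
    if (n_aa < params$min_orf_aa) next
    rows[[length(rows) + 1L]] <- data.frame(
      start_nt = p,
      frame = p %% 3L,
      protein = paste(aa[seq_len(n_aa)], collapse = ""),
      length_aa = n_aa,
      crosses_junction = (p + nt_read) > L,
      cycles = as.integer(ceiling(nt_read / L)),
      rolling_circle = !stopped,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(start_nt = integer(0), frame = integer(0),
                      protein = character(0), length_aa = integer(0),
                      crosses_junction = logical(0), cycles = integer(0),
                      rolling_circle = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the longest circular ORF
#'
#' Rolling-circle frames are excluded (they have no defined product length);
#' among the remaining ORFs the longest protein wins, with ties broken by the
#' smallest start offset, then the smallest frame.
#'
#' @param orfs data.frame from [enumerate_circorfs()]
#' @return single-row data.frame, or `NULL` if no qualifying ORF exists
#' @export
longest_circorf <- function(orfs) {
  if (is.null(orfs) || nrow(orfs) == 0L) return(NULL)
  keep <- orfs[!orfs$rolling_circle, , drop = FALSE]
  if (nrow(keep) == 0L) return(NULL)
  keep <- keep[order(-keep$length_aa, keep$start_nt, keep$frame), , drop = FALSE]
  out <- keep[1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
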