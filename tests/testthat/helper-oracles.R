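# Independent brute-force oracles. Each is deliberately implemented with a
# different strategy than the package code it checks.

# Circular ORF enumeration by scanning the sequence concatenated
# (cycle_cap + 1) times, deduplicated by start position mod L.
oracle_circorfs <- function(seq, min_orf_aa = 1L, cycle_cap = 3L) {
  L <- nchar(seq)
  ext <- strrep(seq, cycle_cap + 1L)
  max_codons <- (cycle_cap * L) %/% 3L
  gc <- Biostrings::GENETIC_CODE
  rows <- list()
  for (p in seq_len(L)) {                    # 1-based start on the circle
    if (substr(ext, p, p + 2L) != "ATG") next
    prot <- character(0)
    stopped <- FALSE
    nt_read <- 0L
    for (k in seq_len(max_codons) - 1L) {
      aa <- unname(gc[substr(ext, p + 3L * k, p + 3L * k + 2L)])
      if (aa == "*") { stopped <- TRUE; nt_read <- 3L * (k + 1L); break }
      prot <- c(prot, aa)
    }
    if (!stopped) nt_read <- 3L * max_codons
    if (length(prot) < min_orf_aa) next
    rows[[length(rows) + 1L]] <- data.frame(
      start_nt = p - 1L, frame = (p - 1L) %% 3L,
      protein = paste(prot, collapse = ""),
      length_aa = length(prot),
      crosses_junction = (p - 1L + nt_read) > L,
      cycles = as.integer(ceiling(nt_read / L)),
      rolling_circle = !stopped, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start_nt = integer(0), frame = integer(0),
                      protein = character(0), length_aa = integer(0),
                      crosses_junction = logical(0), cycles = integer(0),
                      rolling_circle = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Local alignment score oracle: Biostrings' independent implementation.
oracle_sw_score <- function(query, subject, gap_open = 11, gap_extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  max(0, Biostrings::pairwiseAlignment(
    query, subject, type = "local", substitutionMatrix = BLOSUM62,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

# Two-sided Fisher by explicit binomial-coefficient enumeration.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  ks <- max(0L, k - n):min(k, m)
  pr <- choose(m, ks) * choose(n, k - ks) / choose(N, k)
  p0 <- choose(m, a) * choose(n, k - a) / choose(N, k)
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

# Benjamini-Hochberg by the literal step-up definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) min(1, n * p[o[j]] / j), numeric(1))
    adj[o[i]] <- min(cand)
  }
  adj
}

# Quantile normalization by explicit rank bookkeeping (tie-free inputs only).
oracle_quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2L, sort))
  apply(x, 2L, function(col) ref[rank(col)])
}

# Interval overlap by an all-pairs scan (0-based half-open).
oracle_overlap_flags <- function(circ, peaks) {
  strip <- function(z) sub("^chr", "", z)
  flags <- logical(nrow(circ))
  for (i in seq_len(nrow(circ))) {
    for (j in seq_len(nrow(peaks))) {
      if (strip(circ$chrom[i]) == strip(peaks$chrom[j]) &&
          circ$start[i] < peaks$end[j] && peaks$start[j] < circ$end[i]) {
        flags[i] <- TRUE
        break
      }
    }
  }
  setNames(flags, circ$id)
}

# Ordered-containment oracle written recursively (vs the package's loop).
oracle_is_subsequence <- function(a, b) {
  if (!length(a)) return(TRUE)
  if (!length(b)) return(FALSE)
  if (a[1] == b[1]) oracle_is_subsequence(a[-1], b[-1])
  else oracle_is_subsequence(a, b[-1])
}

oracle_domain_class <- function(C, P) {
  if (identical(C, P)) return("conservedStructure")
  if (length(C) == length(P) && identical(sort(C), sort(P)))
    return("differentOrder")
  if (oracle_is_subsequence(P, C)) return("extraDomain")
  if (oracle_is_subsequence(C, P)) return("lackingDomain")
  if (length(intersect(C, P))) return("lackingPlusExtra")
  "novelDomainStructure"
}

# Naive O(n*m) substring scan for peptide matching.
oracle_substring_hits <- function(ext, pep) {
  contains <- function(hay, needle) {
    if (nchar(needle) > nchar(hay)) return(0L)
    for (i in seq_len(nchar(hay) - nchar(needle) + 1L)) {
      if (substr(hay, i, i + nchar(needle) - 1L) == needle) return(i)
    }
    0L
  }
  c(ext_in_db = contains(pep, ext), db_in_ext = contains(ext, pep))
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_peptide <- function(len) {
  paste(sample(setdiff(rownames(get_blosum62()), c("B", "Z", "X", "*")),
               len, replace = TRUE), collapse = "")
}

get_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})
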