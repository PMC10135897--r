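#' Optimal local (Smith-Waterman) protein alignment
#'
#' Exact affine-gap local alignment by dynamic programming. A gap of length
#' `k` costs `gap_open + k * gap_extend` (the BLAST convention: the first gap
#' residue costs `gap_open + gap_extend`). The highest-scoring cell is chosen
#' scanning query positions then subject positions in ascending order, keeping
#' only strict improvements; traceback prefers a diagonal step over a subject
#' gap over a query gap. This makes the reported span deterministic.
#'
#' @param query,subject non-empty protein strings (standard amino acids)
#' @param matrix substitution matrix name (resolved from Biostrings, e.g.
#'   `"BLOSUM62"`) or a numeric matrix
#' @param gap_open,gap_extend gap penalties (positive numbers)
#' @return a `local_alignment` list: `score`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (1-based inclusive spans; all zero when the best score is 0)
#' @export
align_local <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  for (nm in c("query", "subject")) {
    x <- get(nm)
    if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
      stop(nm, " must be a single non-empty string")
  }
  sm <- get_submatrix(matrix)
  q <- chars(query)
  s <- chars(subject)
  bad <- setdiff(unique(c(q, s)), rownames(sm))
  if (length(bad))
    stop("residues absent from the substitution matrix: ",
         paste(bad, collapse = ", "))
  m <- length(q)
  n <- length(s)
  go <- gap_open
  ge <- gap_extend

  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(-Inf, m + 1L, n + 1L) # gap in query (consumes subject)
  F <- matrix(-Inf, m + 1L, n + 1L) # gap in subject (consumes query)
  sub <- sm[q, s, drop = FALSE]

  best <- 0
  bi <- 0L
  bj <- 0L
  for (i in 2:(m + 1L)) {
    Hi1 <- H[i - 1L, ]
    for (j in 2:(n + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - go - ge, E[i, j - 1L] - ge)
      F[i, j] <- max(Hi1[j] - go - ge, F[i - 1L, j] - ge)
      h <- max(0, Hi1[j - 1L] + sub[i - 1L, j - 1L], E[i, j], F[i, j])
      H[i, j] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }

  if (best <= 0) {
    return(structure(list(score = 0, q_start = 0L, q_end = 0L,
                          s_start = 0L, s_end = 0L),
                     class = "local_alignment"))
  }

  ci <- bi
  cj <- bj
  while (H[ci, cj] > 0) {
    h <- H[ci, cj]
    if (ci > 1L && cj > 1L &&
        isTRUE(all.equal(h, H[ci - 1L, cj - 1L] + sub[ci - 1L, cj - 1L]))) {
      ci <- ci - 1L
      cj <- cj - 1L
    } else if (isTRUE(all.equal(h, E[ci, cj]))) {
      k <- 1L
      while (!isTRUE(all.equal(E[ci, cj], H[ci, cj - k] - go - k * ge)))
        k <- k + 1L
      cj <- cj - k
    } else if (isTRUE(all.equal(h, F[ci, cj]))) {
      k <- 1L
      while (!isTRUE(all.equal(F[ci, cj], H[ci - k, cj] - go - k * ge)))
        k <- k + 1L
      ci <- ci - k
    } else {
      stop("internal error: inconsistent traceback")
    }
  }

  structure(list(score = best,
                 q_start = ci, q_end = bi - 1L,
                 s_start = cj, s_end = bj - 1L),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local alignment: score %s, query %d..%d, subject %d..%d\n",
              format(x$score), x$q_start, x$q_end, x$s_start, x$s_end))
  invisible(x)
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * score)` with `m` the query length and `n`
#' the total length of the searched database. Defaults are the standard
#' gapped BLASTP constants for BLOSUM62 with gap penalties 11/1.
#'
#' @param score alignment score
#' @param query_len,db_len sequence and database lengths (>= 1)
#' @param lambda,K Karlin-Altschul parameters (> 0)
#' @return expectation value
#' @export
evalue <- function(score, query_len, db_len, lambda = 0.267, K = 0.041) {
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  if (query_len < 1 || db_len < 1) stop("lengths must be >= 1")
  K * query_len * db_len * exp(-lambda * score)
}

#' Classify N- and C-terminus novelty of a circORF protein
#'
#' Classification uses the local-alignment span boundaries only; substitutions
#' inside the span never create "novel" termini. The 3x3 grid is total and
#' mutually exclusive:
#' \itemize{
#'   \item N side: `canonicalMet` if the alignment starts at residue 1 of both
#'     sequences; `internalMet` if it starts at query residue 1 but inside the
#'     cognate; `N-term` if query residues precede the aligned span (those
#'     residues form the novel N-terminal peptide `n_ext`).
#'   \item C side: `canonicalSTOP` if the alignment ends at the last residue of
#'     both; `prematureTerm` if it ends at the last query residue but inside
#'     the cognate; `C-term` if query residues follow the span (`c_ext`).
#' }
#'
#' @param query_len,cognate_len full protein lengths
#' @param aln a `local_alignment` between the circORF protein (query) and its
#'   cognate linear protein (subject)
#' @param query circORF protein string (used to extract extensions)
#' @return a `terminus_annotation` list: `n_class`, `c_class`, `n_ext`,
#'   `c_ext`, `annotation` (classes joined by `"|"`)
#' @export
annotate_termini <- function(query_len, cognate_len, aln, query) {
  stopifnot(inherits(aln, "local_alignment"))
  if (nchar(query) != query_len)
    stop("query string length does not match query_len")
  if (aln$q_start < 1L || aln$q_end > query_len ||
      aln$s_start < 1L || aln$s_end > cognate_len ||
      aln$q_start > aln$q_end || aln$s_start > aln$s_end)
    stop("alignment spans inconsistent with sequence lengths")

  n_class <- if (aln$q_start == 1L && aln$s_start == 1L) "canonicalMet"
             else if (aln$q_start == 1L) "internalMet"
             else "N-term"
  c_class <- if (aln$q_end == query_len && aln$s_end == cognate_len) "canonicalSTOP"
             else if (aln$q_end == query_len) "prematureTerm"
             else "C-term"
  n_ext <- if (n_class == "N-term") substr(query, 1L, aln$q_start - 1L) else ""
  c_ext <- if (c_class == "C-term") substr(query, aln$q_end + 1L, query_len) else ""

  structure(list(n_class = n_class, c_class = c_class,
                 n_ext = n_ext, c_ext = c_ext,
                 annotation = paste(c_class, n_class, sep = "|")),
            class = "terminus_annotation")
}

#' Best cognate protein for a circORF protein
#'
#' Aligns the query against every cognate isoform and keeps the hit with the
#' lowest E-value (computed against the total cognate database length), ties
#' broken by the highest score, then by lexicographic isoform id.
#'
#' @param query circORF protein string
#' @param cognates named character vector of cognate protein sequences
#' @param matrix,gap_open,gap_extend passed to [align_local()]
#' @param lambda,K passed to [evalue()]
#' @return list with `cognate_id`, `aln`, `evalue`, `cognate_len`, or `NULL`
#'   when `cognates` is empty
#' @export
best_cognate <- function(query, cognates, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1,
                         lambda = 0.267, K = 0.041) {
  if (length(cognates) == 0L) return(NULL)
  if (is.null(names(cognates)) || any(!nzchar(names(cognates))))
    stop("cognates must be a named character vector")
  db_len <- sum(nchar(cognates))
  hits <- lapply(names(cognates), function(id) {
    aln <- align_local(query, cognates[[id]], matrix, gap_open, gap_extend)
    list(cognate_id = id, aln = aln,
         evalue = evalue(aln$score, nchar(query), db_len, lambda, K),
         cognate_len = nchar(cognates[[id]]))
  })
  ord <- order(vapply(hits, `[[`, numeric(1), "evalue"),
               -vapply(hits, function(h) h$aln$score, numeric(1)),
               vapply(hits, `[[`, character(1), "cognate_id"))
  hits[[ord[1L]]]
}

#' Summarise terminus annotations
#'
#' @param annotations list of `terminus_annotation` objects
#' @return list with `counts` (3x3 table of N-class x C-class), `n_ext_mean`,
#'   `n_ext_median`, `c_ext_mean`, `c_ext_median` (means/medians over
#'   non-empty extensions only; `NA` when there are none)
#' @export
extension_stats <- function(annotations) {
  n_levels <- c("canonicalMet", "internalMet", "N-term")
  c_levels <- c("canonicalSTOP", "prematureTerm", "C-term")
  counts <- table(factor(vapply(annotations, `[[`, character(1), "n_class"),
                         levels = n_levels),
                  factor(vapply(annotations, `[[`, character(1), "c_class"),
                         levels = c_levels))
  n_lens <- vapply(annotations, function(a) nchar(a$n_ext), integer(1))
  c_lens <- vapply(annotations, function(a) nchar(a$c_ext), integer(1))
  n_lens <- n_lens[n_lens > 0L]
  c_lens <- c_lens[c_lens > 0L]
  list(counts = counts,
       n_ext_mean = if (length(n_lens)) mean(n_lens) else NA_real_,
       n_ext_median = if (length(n_lens)) median(n_lens) else NA_real_,
       c_ext_mean = if (length(c_lens)) mean(c_lens) else NA_real_,
       c_ext_median = if (length(c_lens)) median(c_lens) else NA_real_)
}
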