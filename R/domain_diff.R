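#' Domain architecture of a protein
#'
#' @param protein_id protein identifier
#' @param domains data.frame with columns `domain_id`, `start`, `end`
#'   (amino-acid coordinates); may have zero rows
#' @return a `domain_architecture` list with the ordered domain-id sequence
#' @export
domain_architecture <- function(protein_id, domains = NULL) {
  if (is.null(domains) || nrow(domains) == 0L) {
    ids <- character(0)
  } else {
    stopifnot(all(c("domain_id", "start", "end") %in% names(domains)))
    if (any(domains$start > domains$end) || any(domains$start < 1))
      stop("malformed domain spans for ", protein_id)
    ids <- as.character(domains$domain_id[order(domains$start, domains$end)])
  }
  structure(list(protein_id = protein_id, domain_ids = ids),
            class = "domain_architecture")
}

# TRUE iff x is a subsequence of y (ordered containment, repeats respected).
is_subsequence <- function(x, y) {
  if (length(x) == 0L) return(TRUE)
  if (length(x) > length(y)) return(FALSE)
  i <- 1L
  for (j in seq_along(y)) {
    if (x[i] == y[j]) {
      i <- i + 1L
      if (i > length(x)) return(TRUE)
    }
  }
  FALSE
}

DOMAIN_CLASSES <- c("conservedStructure", "differentOrder", "lackingDomain",
                    "lackingPlusExtra", "extraDomain", "novelDomainStructure")

#' Compare two domain architectures
#'
#' Works on ordered domain-id sequences `C` (circORF protein) and `P`
#' (cognate linear isoform):
#' \itemize{
#'   \item `conservedStructure`: `C == P` (including both empty);
#'   \item `differentOrder`: same multiset of ids, different order;
#'   \item `extraDomain`: `P` is a proper subsequence of `C`;
#'   \item `lackingDomain`: `C` is a proper subsequence of `P`;
#'   \item `lackingPlusExtra`: at least one shared id, neither a subsequence
#'     of the other;
#'   \item `novelDomainStructure`: no shared ids.
#' }
#' An empty circORF architecture against a non-empty parent is
#' `lackingDomain`; overlap is defined on domain identities, not coordinates.
#'
#' @param circ,linear `domain_architecture` objects
#' @return one of the six class labels
#' @export
compare_pair <- function(circ, linear) {
  C <- circ$domain_ids
  P <- linear$domain_ids
  if (identical(C, P)) return("conservedStructure")
  if (length(C) == length(P) && identical(sort(C), sort(P)))
    return("differentOrder")
  if (is_subsequence(P, C)) return("extraDomain")
  if (is_subsequence(C, P)) return("lackingDomain")
  if (length(intersect(C, P)) > 0L) return("lackingPlusExtra")
  "novelDomainStructure"
}

#' Classify a circORF architecture against all cognate isoforms
#'
#' `novelDomainStructure` is assigned only when the circORF shares no domain
#' with any isoform. Otherwise the call is made against the isoform sharing
#' the largest number of distinct domain ids; remaining ties are broken by
#' class precedence `conservedStructure > extraDomain > lackingDomain >
#' differentOrder > lackingPlusExtra`, then by lexicographic isoform id.
#'
#' @param circ `domain_architecture`
#' @param isoforms non-empty list of `domain_architecture` objects
#' @return list with `class` and `vs_isoform` (`NA` for the novel class)
#' @export
classify_vs_all <- function(circ, isoforms) {
  if (length(isoforms) == 0L) stop("isoform list must be non-empty")
  cls <- vapply(isoforms, function(iso) compare_pair(circ, iso), character(1))
  ids <- vapply(isoforms, `[[`, character(1), "protein_id")
  if (all(cls == "novelDomainStructure"))
    return(list(class = "novelDomainStructure", vs_isoform = NA_character_))
  shared <- vapply(isoforms, function(iso)
    length(intersect(unique(circ$domain_ids), unique(iso$domain_ids))),
    integer(1))
  precedence <- c(conservedStructure = 1L, extraDomain = 2L, lackingDomain = 3L,
                  differentOrder = 4L, lackingPlusExtra = 5L,
                  novelDomainStructure = 6L)
  ord <- order(-shared, precedence[cls], ids)
  pick <- ord[1L]
  list(class = cls[pick], vs_isoform = ids[pick])
}
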