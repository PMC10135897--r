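# Synthetic fixture generator.
#
# The generator works backwards from the answers: it first designs, per
# scenario label, the cognate protein P and the circORF protein Q so that the
# optimal local alignment of Q against P is forced to recover the planted
# terminus classes, then reverse-engineers a genome, annotation and backsplice
# records that reproduce exactly those molecules through the real pipeline.
#
# Two disjoint amino-acid alphabets make the recovery provable rather than
# probable: cognate bodies are drawn from CA and novel extensions from EA,
# chosen so that every EA-vs-CA (and EA-vs-M) BLOSUM62 score is strictly
# negative. A Smith-Waterman alignment can therefore never extend into an
# extension, and the aligned span boundaries are exactly the planted ones.
# Codon choices never end in "A" or "AT", so no ATG can arise across codon
# boundaries: each designed circle carries exactly one ATG and hence exactly
# one ORF.

AA_COGNATE <- c("A", "L", "G", "S", "T", "Q", "N", "D")
AA_EXTENSION <- c("W", "P", "Y")
CODON_TABLE <- c(A = "GCC", L = "CTC", G = "GGC", S = "TCC", T = "ACC",
                 Q = "CAG", N = "AAC", D = "GAC", M = "ATG", W = "TGG",
                 P = "CCG", Y = "TAC")

TERMINUS_LABELS <- c("canonicalMet+C-term", "internalMet+C-term",
                     "N-term+C-term", "canonicalMet+prematureTerm",
                     "internalMet+prematureTerm", "N-term+canonicalSTOP",
                     "canonicalMet+canonicalSTOP", "rollingCircle")

#' Configuration for the synthetic fixture generator
#'
#' Defaults describe a toy world small enough for test suites but exercising
#' every pipeline branch: one circRNA per terminus scenario (the full 3x3
#' grid is reachable; the default covers seven class pairs plus a
#' rolling-circle frame), the six domain-diff classes cycled across coding
#' circRNAs, balanced cancer/normal samples, and four decoy records that each
#' violate exactly one selection filter.
#'
#' @param seed integer random seed; fixed seed implies byte-identical outputs
#' @param n_genes number of annotated genes (must accommodate one gene per
#'   coding circRNA plus four auxiliary genes)
#' @param exons_per_gene length-2 range for the cognate transcript exon count
#' @param exon_len length-2 range (nt) bounding generated exon sizes
#' @param n_circ total backsplice records emitted (coding + decoys)
#' @param n_decoys decoy records violating one selection filter each
#'   (few-samples, intergenic, short, read-through, cycled)
#' @param n_samples number of samples (>= 4)
#' @param frac_cancer proportion of cancer samples, in (0, 1)
#' @param planted_classes terminus scenario labels, cycled over coding
#'   circRNAs; see `TERMINUS_LABELS` for the vocabulary
#' @param de_effect planted log2 fold-change magnitude for DE circRNAs
#' @param noise_sd standard deviation of log2 expression noise
#' @param min_samples_expressed stand-in for the pan-cancer 40-sample filter
#' @param multi_isoform give one gene a second cognate isoform (domain-diff
#'   multi-isoform scenario)
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(seed = 1L, n_genes = 12L,
                             exons_per_gene = c(2L, 4L),
                             exon_len = c(80L, 300L),
                             n_circ = 12L, n_decoys = 4L, n_samples = 60L,
                             frac_cancer = 0.5,
                             planted_classes = TERMINUS_LABELS,
                             de_effect = 2, noise_sd = 0.5,
                             min_samples_expressed = 10L,
                             multi_isoform = FALSE) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len), n_circ = as.integer(n_circ),
              n_decoys = as.integer(n_decoys),
              n_samples = as.integer(n_samples), frac_cancer = frac_cancer,
              planted_classes = planted_classes, de_effect = de_effect,
              noise_sd = noise_sd,
              min_samples_expressed = as.integer(min_samples_expressed),
              multi_isoform = isTRUE(multi_isoform))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$frac_cancer <= 0 || cfg$frac_cancer >= 1)
    stop("frac_cancer must be strictly between 0 and 1")
  if (cfg$de_effect < 0) stop("de_effect must be >= 0")
  if (cfg$exon_len[2] < 40L)
    stop("impossible scenario combination: exon_len upper bound ",
         cfg$exon_len[2], " nt is too short to host a 50-aa ORF piece")
  n_coding <- cfg$n_circ - cfg$n_decoys
  if (n_coding < length(cfg$planted_classes))
    stop("n_circ - n_decoys = ", n_coding, " cannot realize ",
         length(cfg$planted_classes), " planted scenario(s); first missing: ",
         cfg$planted_classes[n_coding + 1L])
  bad <- setdiff(cfg$planted_classes, TERMINUS_LABELS)
  if (length(bad))
    stop("unknown planted scenario label(s): ", paste(bad, collapse = ", "))
  if (cfg$n_genes < n_coding + 4L)
    stop("n_genes must be at least n_circ - n_decoys + 4 (coding genes ",
         "plus short/few-samples decoy genes and two plain genes)")
  invisible(cfg)
}

# ---- low-level sequence builders -------------------------------------------

codons_for <- function(aa) {
  cods <- CODON_TABLE[aa]
  if (anyNA(cods)) stop("no codon assigned for residue(s): ",
                        paste(unique(aa[is.na(cods)]), collapse = ", "))
  paste(cods, collapse = "")
}

random_filler <- function(len) {
  # no "A" anywhere, starts with "C": cannot create an ATG, even at junctions
  paste0("C", paste(sample(c("C", "G", "T"), len - 1L, replace = TRUE),
                    collapse = ""))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Draw an extension peptide that is containment-free against everything drawn
# so far (registry is an environment holding a character vector "seen").
draw_extension <- function(len, registry, prefix = "") {
  for (try in 1:200) {
    cand <- paste0(prefix, paste(sample(AA_EXTENSION, len, replace = TRUE),
                                 collapse = ""))
    seen <- registry$seen
    clash <- any(vapply(seen, function(s)
      grepl(cand, s, fixed = TRUE) || grepl(s, cand, fixed = TRUE),
      logical(1)))
    if (!clash) {
      registry$seen <- c(seen, cand)
      return(cand)
    }
  }
  stop("could not draw a containment-free extension peptide")
}

# Split `total` into `n` chunk lengths, each <= max_len; n is raised if needed.
chunk_lengths <- function(total, n, max_len) {
  n <- max(n, ceiling(total / max_len))
  base <- total %/% n
  sizes <- rep(base, n)
  extra <- total - base * n
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (n > 1L && base > 5L * n + 5L && base + 5L * n <= max_len) {
    jit <- sample(-5:5, n - 1L, replace = TRUE)
    sizes[seq_len(n - 1L)] <- sizes[seq_len(n - 1L)] + jit
    sizes[n] <- total - sum(sizes[seq_len(n - 1L)])
  }
  stopifnot(sum(sizes) == total, all(sizes > 0L), all(sizes <= max_len))
  sizes
}

# ---- scenario design --------------------------------------------------------

# Design cognate protein P and circORF protein Q realizing a terminus label.
design_scenario <- function(label, registry) {
  if (label == "rollingCircle") {
    plen <- sample(70:90, 1L)
    P <- c("M", sample(AA_COGNATE, plen - 1L, replace = TRUE))
    roll <- c("M", sample(AA_COGNATE, 59L, replace = TRUE))
    return(list(label = label, P = P, Q = NULL, roll_aa = roll,
                n_class = NA_character_, c_class = NA_character_,
                n_ext = "", c_ext = "", j = NA_integer_, e = NA_integer_))
  }
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  n_class <- parts[1]
  c_class <- parts[2]
  core_len <- sample(55:75, 1L)
  j <- switch(n_class,
              canonicalMet = 1L,
              internalMet = sample(12:25, 1L),
              `N-term` = sample(5:15, 1L))
  tail_extra <- if (c_class == "canonicalSTOP") 0L else sample(8:20, 1L)
  plen <- (j - 1L) + core_len + tail_extra
  P <- sample(AA_COGNATE, plen, replace = TRUE)
  P[1L] <- "M"
  if (n_class == "internalMet") P[j] <- "M"
  e <- j + core_len - 1L
  core <- P[j:e]
  n_ext <- if (n_class == "N-term")
    draw_extension(max(8L, rpois(1L, 23L)), registry, prefix = "M") else ""
  c_ext <- if (c_class == "C-term")
    draw_extension(max(6L, rpois(1L, 17L)), registry) else ""
  Q <- c(if (nzchar(n_ext)) chars(n_ext), core,
         if (nzchar(c_ext)) chars(c_ext))
  list(label = label, P = P, Q = Q, roll_aa = NULL,
       n_class = n_class, c_class = c_class,
       n_ext = n_ext, c_ext = c_ext, j = j, e = e)
}

# Build the circular spliced sequence for a designed scenario. Returns the
# ordered exonic pieces (transcript orientation) whose concatenation is the
# circle, plus the expected ORF protein.
design_circle <- function(scn) {
  if (scn$label == "rollingCircle") {
    s <- codons_for(scn$roll_aa)          # no stop: length 180, frame repeats
    n <- nchar(s)
    cuts <- c(60L, 120L)
    pieces <- c(substr(s, 1L, cuts[1]), substr(s, cuts[1] + 1L, cuts[2]),
                substr(s, cuts[2] + 1L, n))
    return(list(S = s, pieces = pieces, protein = NULL))
  }
  orf_nt <- paste0(codons_for(scn$Q), "TAA")
  n_cod <- length(scn$Q) + 1L
  sp <- sample(5:(length(scn$Q) - 5L), 1L)  # codons kept on the head piece
  head_nt <- substr(orf_nt, 1L, 3L * sp)
  tail_nt <- substr(orf_nt, 3L * sp + 1L, 3L * n_cod)
  filler <- random_filler(sample(40:90, 1L))
  s <- paste0(tail_nt, filler, head_nt)
  n_atg <- length(gregexpr("ATG", paste0(s, substr(s, 1L, 2L)),
                           fixed = TRUE)[[1]])
  if (n_atg != 1L)
    stop("internal error: designed circle for ", scn$label,
         " carries ", n_atg, " ATG codons")
  list(S = s, pieces = c(tail_nt, filler, head_nt),
       protein = paste(scn$Q, collapse = ""))
}

# ---- gene region layout -----------------------------------------------------

# Lay out one gene region in sense orientation and return genomic-strand
# coordinates. `t2_pieces` may be NULL (plain gene). Interval types: exon
# features carry transcript ids; the circ window spans the t2 exons.
build_gene_region <- function(gene, P, t2_pieces, strand, cfg) {
  cds_nt <- paste0(codons_for(P), "TAA")
  n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1L)
  sizes <- chunk_lengths(nchar(cds_nt), n_ex, cfg$exon_len[2])
  feats <- list()  # local sense-coordinate features
  seq_parts <- character(0)
  pos <- 0L
  push <- function(str, type, transcript) {
    seq_parts[[length(seq_parts) + 1L]] <<- str
    if (!is.na(type))
      feats[[length(feats) + 1L]] <<- list(type = type, start = pos + 1L,
                                           end = pos + nchar(str),
                                           transcript = transcript)
    pos <<- pos + nchar(str)
  }
  off <- 0L
  for (k in seq_along(sizes)) {
    if (k > 1L) push(random_dna(sample(60:140, 1L)), NA, NA)
    push(substr(cds_nt, off + 1L, off + sizes[k]), "exon_t1", "t1")
    off <- off + sizes[k]
  }
  if (!is.null(t2_pieces)) {
    push(random_dna(sample(150:250, 1L)), NA, NA)
    for (k in seq_along(t2_pieces)) {
      if (k > 1L) push(random_dna(sample(60:120, 1L)), NA, NA)
      sub_sizes <- chunk_lengths(nchar(t2_pieces[k]), 1L, cfg$exon_len[2])
      soff <- 0L
      for (m in seq_along(sub_sizes)) {
        if (m > 1L) push(random_dna(sample(60:120, 1L)), NA, NA)
        push(substr(t2_pieces[k], soff + 1L, soff + sub_sizes[m]),
             "exon_t2", "t2")
        soff <- soff + sub_sizes[m]
      }
    }
  }
  region <- paste(seq_parts, collapse = "")
  L <- nchar(region)

  fdf <- do.call(rbind, lapply(feats, function(f)
    data.frame(type = f$type, start = f$start, end = f$end,
               transcript = f$transcript, stringsAsFactors = FALSE)))

  # CDS sub-intervals on the t1 exons (stop codon excluded), with frame.
  t1 <- fdf[fdf$type == "exon_t1", , drop = FALSE]
  cds_len <- nchar(cds_nt) - 3L
  cum <- 0L
  cds_rows <- list()
  for (k in seq_len(nrow(t1))) {
    w <- t1$end[k] - t1$start[k] + 1L
    lo <- cum + 1L
    hi <- cum + w
    if (lo <= cds_len) {
      cds_rows[[length(cds_rows) + 1L]] <- data.frame(
        type = "cds", start = t1$start[k],
        end = t1$start[k] + min(hi, cds_len) - lo,
        transcript = "t1", frame = (3L - (cum %% 3L)) %% 3L,
        stringsAsFactors = FALSE)
    }
    cum <- cum + w
  }
  cds_df <- do.call(rbind, cds_rows)
  fdf$frame <- NA_integer_
  fdf <- rbind(fdf, cds_df)

  if (strand == "-") {
    region <- revcomp(region)
    new_start <- L - fdf$end + 1L
    new_end <- L - fdf$start + 1L
    fdf$start <- new_start
    fdf$end <- new_end
  }
  window <- if (!is.null(t2_pieces)) {
    t2 <- fdf[fdf$type == "exon_t2", , drop = FALSE]
    c(min(t2$start), max(t2$end))
  } else NULL
  list(gene = gene, seq = region, features = fdf, strand = strand,
       window = window, protein = paste(P, collapse = ""))
}

# ---- domain architecture planting ------------------------------------------

plant_domain_arch <- function(class, parent_ids, pool_env) {
  new_id <- function() {
    id <- pool_env$next_id
    pool_env$next_id <- id + 1L
    sprintf("PF%05d", id)
  }
  switch(class,
    conservedStructure = parent_ids,
    lackingDomain = parent_ids[-sample(seq_along(parent_ids), 1L)],
    differentOrder = {
      idx <- seq_along(parent_ids)
      sw <- sample(idx, 2L)
      idx[sw] <- rev(idx[sw])
      parent_ids[idx]
    },
    extraDomain = append(parent_ids, new_id(),
                         after = sample(0:length(parent_ids), 1L)),
    lackingPlusExtra = c(parent_ids[-sample(seq_along(parent_ids), 1L)],
                         new_id()),
    novelDomainStructure = replicate(2L, new_id()),
    stop("unknown domain class: ", class))
}

arch_rows <- function(protein_id, ids) {
  if (length(ids) == 0L)
    return(data.frame(protein_id = character(0), domain_id = character(0),
                      start = integer(0), end = integer(0)))
  data.frame(protein_id = protein_id, domain_id = ids,
             start = 5L + (seq_along(ids) - 1L) * 12L,
             end = 5L + (seq_along(ids) - 1L) * 12L + 7L,
             stringsAsFactors = FALSE)
}

# ---- make_reference ---------------------------------------------------------

#' Generate the synthetic reference world
#'
#' Builds a toy genome, gene annotation, cognate proteins, domain table and
#' circRNA backsplice definitions in which every planted scenario label is
#' realized by construction, and returns a machine-readable truth table for
#' recovery testing.
#'
#' @param config a [synthetic_config()] object
#' @return list with `genome` (named `DNAStringSet`), `gtf` (data.frame of
#'   GTF fields), `proteins` (named character vector of cognate proteins),
#'   `domains` (domain table data.frame), `circs` (backsplice definitions),
#'   `truth` (truth table data.frame)
#' @export
make_reference <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  n_coding <- config$n_circ - config$n_decoys
  labels <- rep(config$planted_classes, length.out = n_coding)
  registry <- new.env()
  registry$seen <- character(0)
  pool_env <- new.env()
  pool_env$next_id <- 1L

  genes <- list()
  truth_rows <- list()
  domain_rows <- list()
  proteins <- character(0)

  domain_cycle <- DOMAIN_CLASSES
  strands <- rep(c("+", "-"), length.out = n_coding)
  di <- 0L

  for (i in seq_len(n_coding)) {
    sym <- sprintf("GENE%03d", i)
    scn <- design_scenario(labels[i], registry)
    circ <- design_circle(scn)
    region <- build_gene_region(sym, scn$P, circ$pieces, strands[i], config)
    genes[[sym]] <- region
    proteins[paste0(sym, ".t1")] <- region$protein

    parent_arch <- sample(sprintf("PF%05d", pool_env$next_id + 0:2))
    pool_env$next_id <- pool_env$next_id + 3L
    domain_rows[[length(domain_rows) + 1L]] <-
      arch_rows(paste0(sym, ".t1"), parent_arch)

    if (is.null(circ$protein)) {
      dclass <- NA_character_
    } else {
      di <- di + 1L
      dclass <- domain_cycle[(di - 1L) %% length(domain_cycle) + 1L]
      circ_arch <- plant_domain_arch(dclass, parent_arch, pool_env)
      domain_rows[[length(domain_rows) + 1L]] <-
        arch_rows(paste0("CIRC", sym), circ_arch)
    }

    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      gene = sym, scenario = labels[i], kind = "coding",
      n_class = scn$n_class, c_class = scn$c_class,
      n_ext = scn$n_ext, c_ext = scn$c_ext,
      protein = circ$protein %||% NA_character_,
      rolling = is.null(circ$protein),
      domain_class = dclass, stringsAsFactors = FALSE)
  }

  # Auxiliary genes: short-circle decoy host, few-samples decoy host, and two
  # adjacent plain genes (read-through target + background-peak host).
  aux_defs <- list(
    list(sym = "GENEDS", t2 = random_dna(100L)),   # short circle (< 150 nt)
    list(sym = "GENEDF", t2 = random_dna(200L)),   # few-samples circle
    list(sym = "GENEP01", t2 = NULL),
    list(sym = "GENEP02", t2 = NULL))
  for (d in aux_defs) {
    P <- c("M", sample(AA_COGNATE, sample(60:80, 1L), replace = TRUE))
    region <- build_gene_region(d$sym, P,
                                if (is.null(d$t2)) NULL else d$t2,
                                "+", config)
    genes[[d$sym]] <- region
    proteins[paste0(d$sym, ".t1")] <- region$protein
  }
  # Extra plain genes up to n_genes.
  n_extra <- config$n_genes - length(genes)
  for (k in seq_len(max(0L, n_extra))) {
    sym <- sprintf("GENEX%02d", k)
    P <- c("M", sample(AA_COGNATE, sample(60:80, 1L), replace = TRUE))
    genes[[sym]] <- build_gene_region(sym, P, NULL, "+", config)
    proteins[paste0(sym, ".t1")] <- genes[[sym]]$protein
  }

  if (config$multi_isoform) {
    # Second cognate isoform for GENE001: a truncated protein (still the
    # worse alignment hit) plus its own domain architecture.
    p1 <- proteins[["GENE001.t1"]]
    p2 <- paste0("M", substr(p1, 12L, nchar(p1)))
    proteins[["GENE001.t1b"]] <- p2
    iso_arch <- c(sprintf("PF%05d", pool_env$next_id),
                  sprintf("PF%05d", pool_env$next_id + 1L))
    pool_env$next_id <- pool_env$next_id + 2L
    domain_rows[[length(domain_rows) + 1L]] <-
      arch_rows("GENE001.t1b", iso_arch)
  }

  # Chromosome layout: coding genes alternate chr1/chr2; the two plain genes
  # sit adjacent on chr1 so a read-through window can span them.
  chrom_of <- character(0)
  syms <- names(genes)
  coding_syms <- syms[seq_len(n_coding)]
  chrom_of[coding_syms] <- rep(c("chr1", "chr2"), length.out = n_coding)
  chrom_of[setdiff(syms, coding_syms)] <- "chr1"

  offsets <- list()
  chrom_seqs <- list()
  gap_intervals <- list()  # per chrom, first intergenic gap (for decoys)
  for (chrom in c("chr1", "chr2")) {
    members <- syms[chrom_of[syms] == chrom]
    parts <- character(0)
    pos <- 0L
    for (sym in members) {
      gap <- random_dna(sample(200:400, 1L))
      if (is.null(gap_intervals[[chrom]]))
        gap_intervals[[chrom]] <- c(pos + 1L, pos + nchar(gap))
      parts <- c(parts, gap)
      pos <- pos + nchar(gap)
      offsets[[sym]] <- pos
      parts <- c(parts, genes[[sym]]$seq)
      pos <- pos + nchar(genes[[sym]]$seq)
    }
    parts <- c(parts, random_dna(250L))
    chrom_seqs[[chrom]] <- paste(parts, collapse = "")
  }

  # GTF assembly.
  gtf_rows <- list()
  for (sym in syms) {
    g <- genes[[sym]]
    chrom <- chrom_of[[sym]]
    off <- offsets[[sym]]
    f <- g$features
    f$start <- f$start + off
    f$end <- f$end + off
    add <- function(feature, start, end, transcript = NA, frame = ".") {
      attr_str <- if (is.na(transcript)) {
        sprintf('gene_id "%s"; gene_name "%s";', sym, sym)
      } else {
        sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s.%s";',
                sym, sym, sym, transcript)
      }
      gtf_rows[[length(gtf_rows) + 1L]] <<- data.frame(
        seqname = chrom, source = "circorf_sim", feature = feature,
        start = start, end = end, score = ".", strand = g$strand,
        frame = as.character(frame), attributes = attr_str,
        stringsAsFactors = FALSE)
    }
    add("gene", min(f$start), max(f$end))
    for (tx in intersect(c("t1", "t2"), unique(f$transcript))) {
      te <- f[f$transcript == tx & f$type != "cds", , drop = FALSE]
      add("transcript", min(te$start), max(te$end), tx)
      te <- te[order(te$start), , drop = FALSE]
      for (k in seq_len(nrow(te))) add("exon", te$start[k], te$end[k], tx)
      tc <- f[f$transcript == tx & f$type == "cds", , drop = FALSE]
      tc <- tc[order(tc$start), , drop = FALSE]
      for (k in seq_len(nrow(tc)))
        add("CDS", tc$start[k], tc$end[k], tx, tc$frame[k])
    }
    genes[[sym]]$abs_window <- if (!is.null(g$window)) g$window + off else NULL
    genes[[sym]]$chrom <- chrom
  }
  gtf <- do.call(rbind, gtf_rows)

  # circRNA backsplice definitions + decoys.
  circ_rows <- list()
  truth <- do.call(rbind, truth_rows)
  truth$chrom <- NA_character_
  truth$start <- NA_integer_
  truth$end <- NA_integer_
  for (i in seq_len(n_coding)) {
    sym <- truth$gene[i]
    w <- genes[[sym]]$abs_window
    truth$chrom[i] <- genes[[sym]]$chrom
    truth$start[i] <- w[1]
    truth$end[i] <- w[2]
  }
  decoy_kinds <- rep(c("few_samples", "intergenic", "short", "readthrough"),
                     length.out = config$n_decoys)
  decoy_rows <- list()
  for (k in seq_along(decoy_kinds)) {
    kind <- decoy_kinds[k]
    row <- switch(kind,
      few_samples = {
        w <- genes[["GENEDF"]]$abs_window
        data.frame(gene = "GENEDF", chrom = genes[["GENEDF"]]$chrom,
                   start = w[1], end = w[2])
      },
      short = {
        w <- genes[["GENEDS"]]$abs_window
        data.frame(gene = "GENEDS", chrom = genes[["GENEDS"]]$chrom,
                   start = w[1], end = w[2])
      },
      intergenic = {
        gap <- gap_intervals[["chr1"]]
        data.frame(gene = "UNANNOT1", chrom = "chr1",
                   start = gap[1] + 10L,
                   end = min(gap[2] - 10L, gap[1] + 110L))
      },
      readthrough = {
        f1 <- genes[["GENEP01"]]
        f2 <- genes[["GENEP02"]]
        m1 <- offsets[["GENEP01"]] + nchar(f1$seq) %/% 2L
        m2 <- offsets[["GENEP02"]] + nchar(f2$seq) %/% 2L
        data.frame(gene = "GENEP01", chrom = "chr1", start = m1, end = m2)
      })
    row$scenario <- paste0("decoy:", kind)
    decoy_rows[[k]] <- row
  }
  decoys <- do.call(rbind, decoy_rows)
  decoy_truth <- data.frame(
    gene = decoys$gene, scenario = decoys$scenario, kind = "decoy",
    n_class = NA_character_, c_class = NA_character_, n_ext = "", c_ext = "",
    protein = NA_character_, rolling = FALSE, domain_class = NA_character_,
    chrom = decoys$chrom, start = decoys$start, end = decoys$end,
    stringsAsFactors = FALSE)
  truth <- rbind(truth, decoy_truth)
  truth$circ_id <- paste0(truth$gene, "|", truth$chrom, ":", truth$start,
                          "-", truth$end)

  genome <- Biostrings::DNAStringSet(unlist(chrom_seqs))
  ref <- list(genome = genome, gtf = gtf, proteins = proteins,
              domains = do.call(rbind, domain_rows),
              circs = truth[, c("circ_id", "gene", "chrom", "start", "end",
                                "scenario")],
              truth = truth)
  class(ref) <- "synthetic_reference"
  ref
}

# ---- make_expression --------------------------------------------------------

#' Generate per-sample backsplice read counts and a sample sheet
#'
#' Counts follow a log-normal-on-log2-scale model: each circRNA has a baseline
#' log2 expression, planted DE circRNAs add/subtract half the effect size per
#' group (so group means differ by exactly `de_effect` before noise), Gaussian
#' noise with `noise_sd` is added, and counts are derived through per-sample
#' library sizes. The few-samples decoy is restricted to fewer samples than
#' `min_samples_expressed`.
#'
#' @param config a [synthetic_config()] object
#' @param truth truth table from [make_reference()] (the generator assigns and
#'   returns DE statuses on it)
#' @return list: `observations` (backsplice TSV rows), `sample_sheet`
#'   (`sample`, `group`), `library_sizes`, `log2_means` (noise-free planted
#'   log2 means, circRNA x sample), `truth` (with `de_status` filled in)
#' @export
make_expression <- function(config, truth) {
  if (config$n_samples < 4L)
    stop("n_samples must be at least 4 for the DE test to be defined")
  set.seed(config$seed + 1L)
  n <- config$n_samples
  n_cancer <- round(config$frac_cancer * n)
  if (n_cancer < 2L || n - n_cancer < 2L)
    stop("each group needs at least two samples")
  samples <- sprintf("S%03d", seq_len(n))
  groups <- setNames(rep(c("cancer", "normal"), c(n_cancer, n - n_cancer)),
                     samples)
  libs <- setNames(round(runif(n, 0.5e6, 2e6)), samples)

  # DE status: cycle up/down/null over DE-eligible coding circRNAs (those
  # with any primary-structure or domain novelty); everything else is null.
  truth$de_status <- "null"
  eligible <- if (config$de_effect == 0) integer(0) else
    which(truth$kind == "coding" & !truth$rolling &
                    (!(truth$n_class == "canonicalMet" &
                       truth$c_class == "canonicalSTOP") |
                     truth$domain_class != "conservedStructure"))
  truth$de_status[eligible] <-
    rep(c("up", "down", "null"), length.out = length(eligible))

  base <- setNames(runif(nrow(truth), 2, 6), truth$circ_id)
  mu <- matrix(rep(base, n), nrow = nrow(truth), dimnames =
                 list(truth$circ_id, samples))
  half <- config$de_effect / 2
  is_cancer <- groups[samples] == "cancer"
  for (i in seq_len(nrow(truth))) {
    if (truth$de_status[i] == "up")
      mu[i, ] <- mu[i, ] + ifelse(is_cancer, half, -half)
    if (truth$de_status[i] == "down")
      mu[i, ] <- mu[i, ] - ifelse(is_cancer, half, -half)
  }

  expressed <- matrix(TRUE, nrow(truth), n,
                      dimnames = list(truth$circ_id, samples))
  few <- which(truth$scenario == "decoy:few_samples")
  if (length(few)) {
    k <- max(1L, config$min_samples_expressed - 1L)
    expressed[few, ] <- FALSE
    expressed[few, seq_len(min(k, n))] <- TRUE
  }

  noise <- matrix(rnorm(length(mu), 0, config$noise_sd), nrow = nrow(mu))
  vals <- mu + noise
  counts <- pmax(round(2^vals * rep(libs, each = nrow(vals)) / 1e6), 1L)
  counts[!expressed] <- 0L

  obs <- list()
  for (i in seq_len(nrow(truth))) {
    on <- which(counts[i, ] > 0L)
    if (!length(on)) next
    obs[[length(obs) + 1L]] <- data.frame(
      chr = truth$chrom[i], start = truth$start[i], end = truth$end[i],
      reads = as.integer(counts[i, on]), symbol = truth$gene[i],
      sample = samples[on], stringsAsFactors = FALSE)
  }
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL
  list(observations = observations,
       sample_sheet = data.frame(sample = samples, group = unname(groups),
                                 stringsAsFactors = FALSE),
       library_sizes = libs, log2_means = mu, truth = truth)
}

# ---- make_annotation_tracks -------------------------------------------------

#' Generate m6A peaks and a peptide database consistent with the truth table
#'
#' Every other coding circRNA is flagged as m6A-overlapping and receives one
#' peak strictly inside its backsplice window; two background peaks are
#' placed inside a plain gene so that non-overlap is also exercised. Half of
#' the novel N-/C-terminal extensions are planted verbatim in the peptide
#' database, alongside decoy peptides guaranteed (by construction) not to
#' match any extension in either containment direction.
#'
#' @param config a [synthetic_config()] object
#' @param ref a `synthetic_reference` from [make_reference()]
#' @return list: `m6a_peaks` (data.frame chrom/start/end, 0-based half-open),
#'   `peptides` (named character vector), `truth` (with `m6a`, `pep_n_in_db`,
#'   `pep_c_in_db` filled in)
#' @export
make_annotation_tracks <- function(config, ref) {
  set.seed(config$seed + 2L)
  truth <- ref$truth
  coding <- which(truth$kind == "coding")
  truth$m6a <- FALSE
  truth$m6a[coding] <- seq_along(coding) %% 2L == 1L

  peaks <- list()
  for (i in which(truth$m6a)) {
    w0 <- truth$start[i] - 1L   # to 0-based half-open
    w1 <- truth$end[i]
    width <- w1 - w0
    p0 <- w0 + max(1L, width %/% 4L)
    p1 <- min(w1 - 1L, p0 + 50L)
    peaks[[length(peaks) + 1L]] <-
      data.frame(chrom = truth$chrom[i], start = p0, end = p1)
  }
  # Background peaks near the GENEP01 gene start: the read-through decoy
  # window begins at the gene's midpoint, so these overlap no circRNA window.
  gtf <- ref$gtf
  gp <- gtf[gtf$feature == "gene" & grepl('"GENEP01"', gtf$attributes), ]
  if (nrow(gp) == 1L) {
    g0 <- gp$start - 1L   # 0-based
    peaks[[length(peaks) + 1L]] <-
      data.frame(chrom = gp$seqname, start = g0 + 10L, end = g0 + 50L)
    peaks[[length(peaks) + 1L]] <-
      data.frame(chrom = gp$seqname, start = g0 + 60L, end = g0 + 100L)
  }
  m6a_peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))

  truth$pep_n_in_db <- FALSE
  truth$pep_c_in_db <- FALSE
  db <- character(0)
  n_idx <- which(nzchar(truth$n_ext))
  c_idx <- which(nzchar(truth$c_ext))
  pick_n <- n_idx[seq_along(n_idx) %% 2L == 1L]
  pick_c <- c_idx[seq_along(c_idx) %% 2L == 1L]
  truth$pep_n_in_db[pick_n] <- TRUE
  truth$pep_c_in_db[pick_c] <- TRUE
  for (i in pick_n) db[paste0("pepN_", truth$gene[i])] <- truth$n_ext[i]
  for (i in pick_c) db[paste0("pepC_", truth$gene[i])] <- truth$c_ext[i]
  registry <- new.env()
  registry$seen <- c(truth$n_ext[nzchar(truth$n_ext)],
                     truth$c_ext[nzchar(truth$c_ext)])
  for (k in 1:3)
    db[sprintf("pepDECOY%02d", k)] <- draw_extension(12L, registry)

  list(m6a_peaks = m6a_peaks, peptides = db, truth = truth)
}

# ---- writers + top-level simulate ------------------------------------------

write_gtf <- function(gtf, path) {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   gtf$seqname, gtf$source, gtf$feature, gtf$start, gtf$end,
                   gtf$score, gtf$strand, gtf$frame, gtf$attributes)
  writeLines(lines, path)
  invisible(path)
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- as.character(seqs[[nm]])
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

write_bed3 <- function(df, path) {
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  invisible(path)
}

#' Generate and write a complete synthetic fixture set
#'
#' Runs [make_reference()], [make_expression()] and
#' [make_annotation_tracks()] under one configuration and writes
#' `genome.fa`, `annotation.gtf`, `cognate_proteins.fa`, `domains.tsv`,
#' `backsplice.tsv`, `samples.tsv`, `m6a_peaks.bed`, `peptides.fa` and
#' `truth.tsv` into `out_dir`. Output bytes are a pure function of `config`.
#'
#' @param config a [synthetic_config()] object
#' @param out_dir output directory (created if needed)
#' @return (invisibly) list with the in-memory objects and `paths`
#' @export
simulate_fixtures <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(config)
  expr <- make_expression(config, ref$truth)
  tracks <- make_annotation_tracks(config, ref)
  truth <- tracks$truth
  truth$de_status <- expr$truth$de_status

  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "annotation.gtf"),
    proteins = file.path(out_dir, "cognate_proteins.fa"),
    domains = file.path(out_dir, "domains.tsv"),
    backsplice = file.path(out_dir, "backsplice.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    m6a = file.path(out_dir, "m6a_peaks.bed"),
    peptides = file.path(out_dir, "peptides.fa"),
    truth = file.path(out_dir, "truth.tsv"))
  write_fasta(as.list(as.character(ref$genome)) |>
                setNames(names(ref$genome)), paths$genome)
  write_gtf(ref$gtf, paths$gtf)
  write_fasta(as.list(ref$proteins), paths$proteins)
  write_tsv(ref$domains, paths$domains)
  write_tsv(expr$observations, paths$backsplice)
  write_tsv(expr$sample_sheet, paths$samples)
  write_bed3(tracks$m6a_peaks, paths$m6a)
  write_fasta(as.list(tracks$peptides), paths$peptides)
  write_tsv(truth, paths$truth)

  invisible(list(config = config, ref = ref, expression = expr,
                 tracks = tracks, truth = truth, paths = paths))
}

#' Simulate a plain expression matrix with planted differential expression
#'
#' A lightweight generator used for statistical calibration: rows are drawn
#' directly on the log2 scale (baseline uniform on [2, 6], plus/minus half the
#' effect per group for planted rows, Gaussian noise), bypassing genome
#' construction.
#'
#' @param n_de number of planted DE rows (alternating up/down)
#' @param n_null number of null rows
#' @param n_per_group samples per group
#' @param de_effect log2 effect size
#' @param noise_sd Gaussian noise standard deviation
#' @param seed random seed
#' @return list: `matrix` (rows x samples, log2 scale), `groups`, `truth`
#'   (data.frame `id`, `de_status`)
#' @export
simulate_de_matrix <- function(n_de = 500L, n_null = 4500L,
                               n_per_group = 30L, de_effect = 2,
                               noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  n_rows <- n_de + n_null
  samples <- sprintf("S%03d", seq_len(2L * n_per_group))
  groups <- setNames(rep(c("cancer", "normal"), each = n_per_group), samples)
  status <- c(if (n_de > 0L) rep(c("up", "down"), length.out = n_de),
              rep("null", n_null))
  ids <- sprintf("row%05d", seq_len(n_rows))
  base <- runif(n_rows, 2, 6)
  delta <- ifelse(status == "up", de_effect / 2,
                  ifelse(status == "down", -de_effect / 2, 0))
  eff <- outer(delta, ifelse(groups == "cancer", 1, -1))
  m <- base + eff + matrix(rnorm(n_rows * length(samples), 0, noise_sd),
                           n_rows)
  dimnames(m) <- list(ids, samples)
  list(matrix = m, groups = groups,
       truth = data.frame(id = ids, de_status = status,
                          stringsAsFactors = FALSE))
}
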