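# Shared toy fixtures, built in code at test time.

# A tiny two-chromosome genome with a three-exon gene G1 (+ strand, chr1),
# its minus-strand mirror G2 on chr2 (identical sequence and coordinates),
# and a second chr1 gene G3 for read-through tests.
toy_reference <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(4242)
    chr1 <- random_dna_str(1000)
    dir <- tempfile("toyref")
    dir.create(dir)
    genome_path <- file.path(dir, "genome.fa")
    writeLines(c(">chr1", chr1, ">chr2", chr1), genome_path)
    gtf_path <- file.path(dir, "genes.gtf")
    gl <- function(chrom, feat, s, e, strand, gene, tx) {
      attrs <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                       gene, gene, tx)
      sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\t%s",
              chrom, feat, s, e, strand, attrs)
    }
    exons1 <- list(c(101L, 200L), c(301L, 400L), c(501L, 600L))
    lines <- c(
      gl("chr1", "gene", 101, 600, "+", "G1", "G1.t1"),
      gl("chr1", "transcript", 101, 600, "+", "G1", "G1.t1"),
      unlist(lapply(exons1, function(z)
        gl("chr1", "exon", z[1], z[2], "+", "G1", "G1.t1"))),
      gl("chr2", "gene", 101, 600, "-", "G2", "G2.t1"),
      gl("chr2", "transcript", 101, 600, "-", "G2", "G2.t1"),
      unlist(lapply(exons1, function(z)
        gl("chr2", "exon", z[1], z[2], "-", "G2", "G2.t1"))),
      gl("chr1", "gene", 700, 900, "+", "G3", "G3.t1"),
      gl("chr1", "transcript", 700, 900, "+", "G3", "G3.t1"),
      gl("chr1", "exon", 700, 900, "+", "G3", "G3.t1"))
    writeLines(lines, gtf_path)
    cache <<- list(
      genome = Biostrings::readDNAStringSet(genome_path),
      genome_path = genome_path, gtf_path = gtf_path,
      annotation = circorf::read_annotation(gtf_path),
      chr1 = chr1, exons = exons1)
    names(cache$genome) <<- c("chr1", "chr2")
    cache
  }
})

toy_record <- function(gene, chrom, start, end, samples_expressed = 50L) {
  data.frame(circ_id = paste0(gene, "|", chrom, ":", start, "-", end),
             gene = gene, chrom = chrom, start = as.integer(start),
             end = as.integer(end),
             samples_expressed = as.integer(samples_expressed),
             stringsAsFactors = FALSE)
}

# One noiseless synthetic fixture set + pipeline run, shared across tests.
noiseless_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- circorf::synthetic_config(seed = 11L, noise_sd = 0,
                                     min_samples_expressed = 10L)
    dir <- tempfile("fx")
    fx <- circorf::simulate_fixtures(cfg, dir)
    pc <- circorf::pipeline_config(
      genome = fx$paths$genome, gtf = fx$paths$gtf,
      proteins = fx$paths$proteins, backsplice = fx$paths$backsplice,
      sample_sheet = fx$paths$samples, domains = fx$paths$domains,
      m6a_bed = fx$paths$m6a, peptides = fx$paths$peptides,
      out_dir = file.path(dir, "out"),
      min_samples = 10L, apply_sample_filter = FALSE)
    cache <<- list(cfg = cfg, fx = fx, pc = pc,
                   summary = circorf::run_pipeline(pc))
    cache
  }
})
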