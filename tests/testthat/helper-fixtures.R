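# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk.

# quadripartite genome with exact planted structure and junction breakers so
# the maximal IR equals the planted arm exactly
make_quadripartite <- function(lsc = 2000, ir = 800, ssc = 300, gc = 0.4) {
  fix_ends <- function(s) {            # first base must not complement last
    last <- substr(s, nchar(s), nchar(s))
    bad <- chartr("ACGT", "TGCA", last)
    if (substr(s, 1, 1) == bad)
      substr(s, 1, 1) <- setdiff(c("A", "C", "G", "T"), bad)[1]
    s
  }
  L <- fix_ends(random_dna_str(lsc, gc))
  I <- random_dna_str(ir, gc)
  S <- fix_ends(random_dna_str(ssc, gc))
  paste0(L, I, S, oracle_revcomp(I))
}

# tiny annotated record: two genes on a linear-ish backbone
make_two_gene_record <- function(gap = 50) {
  n <- 30 + 30 + gap + 30 + 30
  seqs <- random_dna_str(n)
  feats <- feature_table(
    gene_feature("geneA", "CDS", 31, 60),
    gene_feature("geneB", "CDS", 60 + gap + 1, 60 + gap + 30))
  plastome_record("two", seqs, circular = FALSE, features = feats)
}

# reverse-complemented record with mirrored features (for strand properties)
revcomp_record <- function(record) {
  n <- record$length
  f <- record$features
  rows <- lapply(seq_len(nrow(f)), function(i) {
    p <- f$parts[[i]]
    p2 <- cbind(start = n - p[, 2] + 1L, end = n - p[, 1] + 1L)
    p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
    gene_feature(f$name[i], f$kind[i], parts = p2,
                 strand = if (f$strand[i] == "+") "-" else "+",
                 pseudo = f$pseudo[i], partial = f$partial[i])
  })
  plastome_record(record$id, oracle_revcomp(record$sequence),
                  record$circular, do.call(rbind, rows))
}

# small synthetic plastome spec used throughout the tests
small_sim_spec <- function(seed, ...) {
  synthetic_plastome_spec(seed = seed, lsc = 6000, ir = 2500, ssc = 1200, ...)
}

# minimal GenBank flat-file text for parser tests; sequence laid out so the
# CDS at 4..12 is ATGAAATAA and a pseudo gene feature sits at 25..30
minimal_genbank_text <- function() {
  seqs <- paste0("CCC", "ATGAAATAA", "T", "GGGGGGGGGG", "A", "CCCCCC", "TTT")
  stopifnot(nchar(seqs) == 33)
  blocks <- substring(tolower(seqs), seq(1, 33, 10), pmin(seq(10, 42, 10), 33))
  c("LOCUS       testrec 33 bp    DNA     circular PLN 01-JAN-2000",
    "DEFINITION  minimal fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..33",
    "     CDS             4..12",
    '                     /gene="tiny"',
    "     tRNA            complement(14..23)",
    '                     /gene="trnX-ABC"',
    "     gene            25..30",
    '                     /gene="ndhQ"',
    "                     /pseudo",
    "ORIGIN",
    paste0("        1 ", paste(blocks, collapse = " ")),
    "//")
}
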