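test_that("GenBank parsing captures sequence, locations and pseudo flags", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(minimal_genbank_text(), path)
  rec <- read_genbank(path)
  expect_s3_class(rec, "plastome_record")
  expect_equal(rec$length, 33L)
  expect_true(rec$circular)
  expect_equal(nrow(rec$features), 3L)
  cds <- extract_cds(rec)
  expect_equal(cds$gene, "tiny")
  expect_equal(cds$seq, "ATGAAATAA")
  trna <- rec$features[rec$features$kind == "tRNA", ]
  expect_equal(trna$strand, "-")
  expect_true(rec$features$pseudo[rec$features$name == "ndhQ"])
})

test_that("parse errors are raised for missing sequence and bad intervals", {
  path <- withr::local_tempfile(fileext = ".gb")
  txt <- minimal_genbank_text()
  writeLines(txt[1:11], path)            # no ORIGIN block
  expect_error(read_genbank(path), "ORIGIN|sequence")
  txt2 <- sub("4\\.\\.12", "4..99", txt) # beyond the 33 bp sequence
  writeLines(txt2, path)
  expect_error(read_genbank(path), "tiny")
})

test_that("origin-spanning joined CDS equals the rotate-then-slice oracle", {
  set.seed(101)
  for (trial in 1:10) {
    n <- 60
    backbone <- random_dna_str(n)
    # plant a CDS split across the origin: tail piece then head piece
    tail_len <- sample(3:9, 1) * 1L
    cds_seq <- random_cds(8)                       # 24 bp
    head_len <- nchar(cds_seq) - tail_len
    s <- paste0(substr(cds_seq, nchar(cds_seq) - tail_len + 1, nchar(cds_seq)),
                substr(backbone, tail_len + 1, n - head_len),
                substr(cds_seq, 1, head_len))
    rec <- plastome_record("wrap", s, circular = TRUE,
      features = gene_feature("g", "CDS",
                              parts = rbind(c(n - head_len + 1, n),
                                            c(1, tail_len))))
    # oracle: rotate so the feature is contiguous, then slice
    rot <- paste0(substr(s, n - head_len + 1, n), substr(s, 1, n - head_len))
    expect_equal(extract_cds(rec)$seq, substr(rot, 1, nchar(cds_seq)))
  }
})

test_that("CDS extraction filters pseudogenes, deduplicates IR copies and reports rejects", {
  set.seed(31)
  fill <- strrep("C", 10)
  s <- paste0(fill, random_cds(10), fill, random_cds(10), fill,
              random_cds(10), fill, random_cds(10), strrep("C", 40))
  feats <- feature_table(
    gene_feature("psbA", "CDS", 11, 40),
    gene_feature("rpl2", "CDS", 51, 80),
    gene_feature("ndhB", "CDS", 91, 120, pseudo = TRUE),
    gene_feature("rpl2", "CDS", 131, 160))
  rec <- plastome_record("fx", s, circular = FALSE, features = feats)
  cds <- extract_cds(rec, dedupe_ir_copies = TRUE)
  expect_setequal(cds$gene, c("psbA", "rpl2"))
  cds_all <- extract_cds(rec, dedupe_ir_copies = FALSE)
  expect_equal(sum(cds_all$gene == "rpl2"), 2L)
  # a CDS with broken frame is rejected with a warning
  feats2 <- rbind(feats, gene_feature("badG", "CDS", 185, 194))
  rec2 <- plastome_record("fx2", rec$sequence, FALSE, feats2)
  expect_warning(cds2 <- extract_cds(rec2), "divisible by 3")
  expect_false("badG" %in% cds2$gene)
  expect_true("badG" %in% attr(cds2, "rejects")$gene)
})

test_that("CDS extraction equals an independent feature walk on random fixtures", {
  set.seed(7)
  for (trial in 1:20) {
    n_genes <- sample(2:5, 1)
    pieces <- character(0); feats <- list(); pos <- 1L
    for (g in seq_len(n_genes)) {
      gap <- sample(5:20, 1)
      body <- random_cds(sample(4:10, 1))
      strand <- sample(c("+", "-"), 1)
      pieces <- c(pieces, random_dna_str(gap),
                  if (strand == "+") body else oracle_revcomp(body))
      feats[[g]] <- gene_feature(paste0("g", g), "CDS",
                                 pos + gap, pos + gap + nchar(body) - 1L,
                                 strand = strand)
      pos <- pos + gap + nchar(body)
    }
    s <- paste0(paste(pieces, collapse = ""), random_dna_str(10))
    rec <- plastome_record("rand", s, FALSE, do.call(rbind, feats))
    got <- extract_cds(rec)
    # oracle: re-walk every CDS feature's parts directly
    want <- vapply(seq_len(nrow(rec$features)), function(i) {
      p <- rec$features$parts[[i]]
      raw <- paste(substring(s, p[, 1], p[, 2]), collapse = "")
      if (rec$features$strand[i] == "-") oracle_revcomp(raw) else raw
    }, character(1))
    expect_equal(got$seq, want)
  }
})

test_that("reverse-complementing a record leaves the CDS set unchanged", {
  sim <- generate_plastome(small_sim_spec(3), screen = FALSE)
  a <- extract_cds(sim$record, dedupe_ir_copies = FALSE)
  b <- extract_cds(revcomp_record(sim$record), dedupe_ir_copies = FALSE)
  expect_setequal(a$seq, b$seq)
  expect_setequal(a$gene, b$gene)
})

test_that("gene and IGS loci follow the gap definition", {
  rec <- make_two_gene_record(gap = 50)
  loci <- extract_loci(rec)
  expect_setequal(loci$name, c("geneA", "geneA-geneB", "geneB"))
  igs <- loci[loci$kind == "IGS", ]
  expect_equal(nchar(igs$seq), 50L)
  # abutting genes emit no IGS between them
  rec0 <- make_two_gene_record(gap = 0)
  expect_false(any(extract_loci(rec0)$kind == "IGS"))
})

test_that("IGS loci equal the interval complement of the feature cover", {
  set.seed(21)
  for (trial in 1:15) {
    n <- 400L
    k <- sample(2:5, 1)
    starts <- sort(sample(seq(10, n - 60, by = 5), k))
    feats <- lapply(seq_len(k), function(i)
      gene_feature(paste0("g", i), "CDS", starts[i],
                   starts[i] + sample(10:30, 1)))
    rec <- plastome_record("cmp", random_dna_str(n), circular = FALSE,
                           features = do.call(rbind, feats))
    loci <- extract_loci(rec)
    igs <- loci[loci$kind == "IGS", c("start", "end")]
    ext <- t(vapply(seq_len(nrow(rec$features)), function(i)
      plastomics:::feature_extent(rec, i), numeric(2)))
    gaps <- oracle_igs_intervals(ext, n)
    # drop the flanks (before the first / after the last feature): a linear
    # record has no closing spacer
    gaps <- gaps[gaps[, 1] > min(ext[, 1]) & gaps[, 2] < max(ext[, 2]), ,
                 drop = FALSE]
    expect_equal(unname(as.matrix(igs)), unname(gaps))
  }
})

test_that("gene inventory arithmetic holds and pseudogenes are separated", {
  sim <- generate_plastome(small_sim_spec(5), screen = FALSE)
  inv <- count_genes(sim$record)
  f <- sim$record$features[!sim$record$features$pseudo, ]
  expect_equal(inv$total_genes, nrow(f))
  expect_equal(inv$unique_genes, length(unique(f$name)))
  expect_equal(inv$unique_genes + inv$duplicated_genes, inv$total_genes)
  expect_equal(sum(inv$by_kind), inv$unique_genes)
  # empty record
  empty <- plastome_record("e", "ACGT")
  inv0 <- count_genes(empty)
  expect_equal(inv0$total_genes, 0L)
  expect_equal(unname(inv0$by_kind), c(0L, 0L, 0L))
})

test_that("GenBank writing round-trips sequence and feature set", {
  sim <- generate_plastome(small_sim_spec(9), screen = FALSE)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$record, path)
  back <- read_genbank(path)
  expect_identical(back$sequence, sim$record$sequence)
  expect_identical(back$circular, sim$record$circular)
  expect_equal(back$features, sim$record$features)
})

test_that("FASTA round-trips through Biostrings", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(a = random_dna_str(80), b = random_dna_str(40))
  write_fasta(seqs, path)
  expect_identical(read_fasta(path), seqs)
})
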