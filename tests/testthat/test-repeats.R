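test_that("SSR thresholds are respected at the boundary", {
  flank1 <- "GACTGTCAGGTCACGTGCAG"   # repeat-free flanks
  flank2 <- "CTGACGTTGACGCATGGACT"
  s10 <- paste0(flank1, strrep("A", 10), flank2)
  got <- find_ssrs(s10)
  expect_equal(nrow(got), 1L)
  expect_equal(got$motif, "A")
  expect_equal(got$repeat_count, 10L)
  expect_equal(c(got$start, got$end), c(21L, 30L))
  s9 <- paste0(flank1, strrep("A", 9), flank2)
  expect_equal(nrow(find_ssrs(s9)), 0L)
})

test_that("runs are reported at their smallest primitive unit only", {
  s <- paste0("GGCCGGCC", strrep("AT", 7), "GGCCGGCC")  # AT x 7
  got <- find_ssrs(s)
  expect_equal(nrow(got), 1L)
  expect_equal(got$canonical_class, "AT/AT")
  expect_equal(got$unit_length, 2L)
  expect_equal(got$repeat_count, 7L)
  # a poly-A run never surfaces as a dinucleotide "AA"
  s2 <- paste0("GCGCGGC", strrep("A", 14), "GCGGCGC")
  got2 <- find_ssrs(s2)
  expect_equal(got2$unit_length, 1L)
  expect_equal(got2$repeat_count, 14L)
})

test_that("every reported SSR re-verifies as motif x count and detection is rotation invariant", {
  sim <- generate_plastome(small_sim_spec(
    23, planted_ssrs = data.frame(motif = c("A", "AT", "AATG"),
                                  count = c(11, 6, 4),
                                  region = c("LSC", "SSC", "LSC"))))
  s <- sim$record$sequence
  ssrs <- find_ssrs(s)
  for (i in seq_len(nrow(ssrs))) {
    expect_equal(substr(s, ssrs$start[i], ssrs$end[i]),
                 strrep(ssrs$motif[i], ssrs$repeat_count[i]))
  }
  # rotation invariance with circular scanning
  n <- nchar(s)
  base_classes <- sort(paste(ssrs$canonical_class, ssrs$repeat_count))
  for (off in c(997, n %/% 2)) {
    rot <- paste0(substr(s, off + 1, n), substr(s, 1, off))
    rs <- find_ssrs(rot, circular = TRUE)
    expect_equal(sort(paste(rs$canonical_class, rs$repeat_count)),
                 base_classes)
  }
})

test_that("canonical motif classes follow the rotation/reverse-complement rule", {
  expect_equal(canonical_motif("T"), "A/T")
  expect_equal(canonical_motif("A"), "A/T")
  expect_equal(canonical_motif("AT"), "AT/AT")
  expect_equal(canonical_motif("TTA"), "AAT/ATT")
  expect_equal(canonical_motif("TA"), "AT/AT")    # rotation of AT
  expect_equal(canonical_motif("AAAT"), "AAAT/ATTT")
  expect_error(canonical_motif("AXT"), "A,C,G,T")
  # derived by enumeration: all rotations of motif and its reverse complement
  set.seed(51)
  for (trial in 1:20) {
    u <- sample(1:6, 1)
    m <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE),
               collapse = "")
    rots <- function(x) {
      d <- paste0(x, x)
      substring(d, 1:nchar(x), 1:nchar(x) + nchar(x) - 1)
    }
    want <- paste(sort(c(min(rots(m)), min(rots(oracle_revcomp(m))))),
                  collapse = "/")
    expect_equal(canonical_motif(m), want)
  }
})

test_that("SSR locations classify by region and exon/intron/IGS context", {
  set.seed(52)
  g <- make_quadripartite(lsc = 3000, ir = 700, ssc = 400)
  # exon SSR inside a CDS part; intron SSR between two parts; IGS elsewhere
  feats <- feature_table(
    gene_feature("geneI", "CDS", parts = rbind(c(101, 220), c(501, 620))))
  s <- paste0(substr(g, 1, 140), strrep("A", 12), substr(g, 153, nchar(g)))
  s <- paste0(substr(s, 1, 300), strrep("T", 12), substr(s, 313, nchar(s)))
  s <- paste0(substr(s, 1, 900), strrep("A", 12), substr(s, 913, nchar(s)))
  rec <- plastome_record("ctx", s, TRUE, feats)
  part <- partition_from_lengths(3000, 700, 400,
                                 genome_length = rec$length)
  ssrs <- find_ssrs(s)
  cls <- classify_ssr_location(ssrs, rec, part)
  ctx_of <- function(pos) cls$context[cls$start <= pos & cls$end >= pos]
  expect_equal(ctx_of(145), "exon")
  expect_equal(ctx_of(305), "intron")
  expect_equal(ctx_of(905), "IGS")
  expect_true(all(cls$region %in% c("LSC", "IRb", "SSC", "IRa")))
  # tallies partition the SSR set
  expect_equal(sum(table(cls$region)), nrow(cls))
  expect_equal(sum(table(cls$context)), nrow(cls))
})

test_that("planted dispersed repeats of each kind are found and verified", {
  set.seed(53)
  for (kind in c("F", "R", "P", "C")) {
    arm <- random_dna_str(40)
    arm2 <- switch(kind, F = arm,
                   R = paste(rev(strsplit(arm, "")[[1]]), collapse = ""),
                   P = oracle_revcomp(arm),
                   C = chartr("ACGT", "TGCA", arm))
    s <- paste0(random_dna_str(500), arm, random_dna_str(400), arm2,
                random_dna_str(500))
    got <- find_dispersed_repeats(s, min_length = 35, max_mismatch = 0,
                                  kinds = kind)
    expect_gte(nrow(got), 1L)
    top <- got[1, ]
    expect_equal(top$kind, kind)
    expect_gte(top$length, 40L)
    expect_lte(top$start1, 501L)
    expect_equal(verify_repeat(s, top$kind, top$start1, top$end1,
                               top$start2, top$end2), top$mismatches)
  }
})

test_that("mismatched repeats re-verify within their reported Hamming distance", {
  set.seed(54)
  for (trial in 1:10) {
    arm <- random_dna_str(45)
    arm_mut <- arm
    for (i in sample(5:40, 2))
      substr(arm_mut, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(arm, i, i)), 1)
    s <- paste0(random_dna_str(300), arm, random_dna_str(200), arm_mut,
                random_dna_str(300))
    got <- find_dispersed_repeats(s, min_length = 40, max_mismatch = 3,
                                  kinds = "F")
    expect_gte(nrow(got), 1L)
    for (i in seq_len(nrow(got))) {
      expect_lte(verify_repeat(s, got$kind[i], got$start1[i], got$end1[i],
                               got$start2[i], got$end2[i]), 3L)
    }
  }
})

test_that("exact dispersed-repeat search agrees with the O(n^2) oracle", {
  set.seed(55)
  for (trial in 1:15) {
    kind <- sample(c("F", "R", "P", "C"), 1)
    arm_len <- sample(25:40, 1)
    arm <- random_dna_str(arm_len)
    arm2 <- switch(kind, F = arm,
                   R = paste(rev(strsplit(arm, "")[[1]]), collapse = ""),
                   P = oracle_revcomp(arm),
                   C = chartr("ACGT", "TGCA", arm))
    s <- paste0(random_dna_str(120), arm, random_dna_str(80), arm2,
                random_dna_str(100))
    want <- oracle_dispersed(s, kind, min_length = 20)
    got <- find_dispersed_repeats(s, min_length = 20, max_mismatch = 0,
                                  kinds = kind)
    expect_equal(got[, c("kind", "length", "start1", "end1", "start2",
                         "end2")],
                 want[, c("kind", "length", "start1", "end1", "start2",
                          "end2")],
                 ignore_attr = TRUE)
  }
})

test_that("the IR self-match is masked when a partition is supplied", {
  set.seed(56)
  g <- make_quadripartite(lsc = 2500, ir = 900, ssc = 350)
  part <- detect_inverted_repeats(g, min_ir_length = 300)
  unmasked <- find_dispersed_repeats(g, min_length = 30, max_mismatch = 0)
  expect_true(any(unmasked$kind == "P" & unmasked$length >= 900))
  masked <- find_dispersed_repeats(g, min_length = 30, max_mismatch = 0,
                                   mask_partition = part)
  expect_false(any(masked$kind == "P" & masked$length >= 900))
})
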