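test_that("codon alignment is the identity for identical CDSs", {
  s <- random_cds(20)
  al <- align_codons(s, s)
  expect_equal(al$codons1, al$codons2)
  expect_equal(al$n_codons, 19L)   # terminal stop stripped
  expect_equal(al$identity, 1)
})

test_that("an in-frame codon insertion is removed and flanks stay aligned", {
  set.seed(71)
  base <- random_cds(30)
  cods <- substring(base, seq(1, nchar(base) - 2, 3), seq(3, nchar(base), 3))
  ins <- c(cods[1:15], "TGG", cods[16:length(cods)])   # insert one Trp codon
  s2 <- paste(ins, collapse = "")
  al <- align_codons(base, s2)
  expect_equal(al$n_codons, 29L)                        # 30 - stop
  expect_equal(al$codons1, split_codons_oracle(base)[seq_len(29)])
  expect_equal(al$codons1, al$codons2)                  # insertion removed
})

test_that("back-mapped codon columns equal protein-level indices times three", {
  set.seed(72)
  for (trial in 1:10) {
    a <- random_cds(25)
    b <- mutate_neutral(a, 0.05)
    al <- align_codons(a, b)
    # no indels: mapping must be the identity on both sides
    expect_equal(al$codons1, split_codons_oracle(a)[seq_len(al$n_codons)])
    expect_equal(al$codons2, split_codons_oracle(b)[seq_len(al$n_codons)])
  }
})

test_that("NG86 site counts match the enumeration oracle and sum to 3 per codon", {
  sites <- plastomics:::ng86_syn_sites()
  sense <- plastomics:::sense_codons()
  for (cod in sense) {
    expect_equal(unname(sites[cod]), oracle_syn_sites(cod), tolerance = 1e-12)
    expect_lte(sites[[cod]], 3)
  }
  # synonymous + nonsynonymous sites = 3 for every codon
  expect_equal(unname(sites[sense] + (3 - sites[sense])), rep(3, length(sense)))
})

test_that("NG86 pathway-averaged differences match brute enumeration", {
  set.seed(73)
  sense <- plastomics:::sense_codons()
  for (trial in 1:100) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    got <- plastomics:::ng86_diffs(c1, c2)
    want <- oracle_ng86_diffs(c1, c2)
    expect_equal(unname(got), want, tolerance = 1e-12)
    nd <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    expect_equal(sum(got), nd)   # path steps = number of differing positions
  }
})

test_that("Ka/Ks classifies the canonical small examples", {
  # identical sequences: no rate, excluded
  s <- random_cds(20)
  r0 <- kaks_ng86(align_codons(s, s))
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)
  expect_true(r0$excluded)
  # single synonymous difference: Sd = 1, Nd = 0
  r1 <- kaks_ng86(align_codons("ATGGAT", "ATGGAC"))
  expect_equal(r1$syn_diffs, 1)
  expect_equal(r1$nonsyn_diffs, 0)
  expect_equal(r1$ka, 0)
  # the same difference diluted in a longer gene: Ks > 0, ratio 0
  pad <- strrep("GGT", 20)
  r2 <- kaks_ng86(align_codons(paste0("ATG", pad, "GAT"),
                               paste0("ATG", pad, "GAC")))
  expect_gt(r2$ks, 0)
  expect_equal(r2$ka, 0)
  expect_equal(r2$ratio, 0)
  expect_false(r2$excluded)
})

test_that("Ka/Ks is symmetric and Ka grows with added nonsynonymous changes", {
  set.seed(74)
  a <- random_cds(60)
  b <- mutate_neutral(a, 0.06)
  rab <- kaks_ng86(align_codons(a, b))
  rba <- kaks_ng86(align_codons(b, a))
  expect_equal(rab$ka, rba$ka, tolerance = 1e-12)
  expect_equal(rab$ks, rba$ks, tolerance = 1e-12)
  # layering extra nonsynonymous substitutions strictly increases Ka
  gc11 <- genetic_code_11()
  cods <- split_codons_oracle(b)
  kas <- c()
  for (extra in c(0, 3, 6)) {
    cc <- cods
    idx <- seq_len(extra)
    for (i in idx) {
      for (alt_b in c("A", "C", "G", "T")) {
        cand <- cc[i + 1]
        substr(cand, 1, 1) <- alt_b
        if (gc11[[cand]] != "*" && gc11[[cand]] != gc11[[cc[i + 1]]] &&
            cand != cods[i + 1]) { cc[i + 1] <- cand; break }
      }
    }
    kas <- c(kas, kaks_ng86(align_codons(a, paste(cc, collapse = "")))$ka)
  }
  expect_true(all(diff(kas) > 0))
})

test_that("neutral simulation recovers a Ka/Ks ratio near one", {
  # mean over replicates controls Monte-Carlo error; each replicate is a
  # 10,000-codon pair mutated at equal per-site rates
  set.seed(75)
  ratios <- vapply(1:5, function(i) {
    a <- random_cds(10000)
    b <- mutate_neutral(a, 0.04)
    kaks_ng86(align_codons(a, b))$ratio
  }, numeric(1))
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
})

test_that("the exclusion rule removes undefined and extreme ratios", {
  set.seed(76)
  # nonsynonymous-only divergence on a gene with no synonymous change
  a <- random_cds(2000)
  sim <- list(rec = a)
  gc11 <- genetic_code_11()
  cods <- split_codons_oracle(a)
  for (i in sample(seq_along(cods)[-c(1, length(cods))], 250)) {
    for (alt_b in c("A", "C", "G", "T")) {
      cand <- cods[i]
      substr(cand, 1, 1) <- alt_b
      if (gc11[[cand]] != "*" && gc11[[cand]] != gc11[[cods[i]]]) {
        cods[i] <- cand; break
      }
    }
  }
  b <- paste(cods, collapse = "")
  r <- kaks_ng86(align_codons(a, b))
  expect_true(r$excluded)   # Ks = 0 -> NA, or ratio above the cutoff
})

test_that("the pairwise matrix covers shared genes and labels the method", {
  sim <- generate_plastome(small_sim_spec(77), screen = FALSE)
  div <- mutate_orthologs(sim$record, syn_rate = 0.08, nonsyn_rate = 0.015,
                          igs_rate = 0, seed = 78)
  m <- pairwise_kaks_matrix(list(sim$record, div$record))
  funct <- unique(sim$record$features$name[
    sim$record$features$kind == "CDS" & !sim$record$features$pseudo])
  expect_setequal(m$gene, funct)
  expect_true(all(m$method == "NG86"))
  # purifying-style simulation: nonsynonymous rate well below synonymous
  ok <- !m$excluded
  expect_true(mean(m$ratio[ok]) < 1)
  # absent gene handling
  m2 <- pairwise_kaks_matrix(list(sim$record, div$record),
                             gene_list = c(funct[1], "ghostGene"))
  expect_true(m2$excluded[m2$gene == "ghostGene"])
  expect_equal(m2$reason[m2$gene == "ghostGene"], "absent")
})

test_that("the approximate kappa-weighted estimator stays close to NG86 on neutral data", {
  set.seed(79)
  a <- random_cds(3000)
  b <- mutate_neutral(a, 0.04)
  al <- align_codons(a, b)
  r1 <- kaks_ng86(al)
  r2 <- kaks_yn_approx(al)
  expect_equal(r2$method, "YN-approx")
  expect_lt(abs(r2$ratio - r1$ratio), 0.35)
  expect_gt(r2$ks, 0)
})
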