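test_that("codon counting matches direct tallies and the 3-mer walk oracle", {
  tb <- codon_counts("ATGAAAAAAAAGTAA")
  expect_equal(tb$count[tb$codon == "AAA"], 2L)
  expect_equal(tb$count[tb$codon == "AAG"], 1L)
  expect_equal(tb$count[tb$codon == "ATG"], 1L)
  expect_error(codon_counts(character(0)), "empty")
  set.seed(41)
  for (trial in 1:20) {
    seqs <- vapply(seq_len(sample(1:4, 1)),
                   function(i) random_cds(sample(5:40, 1)), character(1))
    got <- codon_counts(seqs)
    want <- oracle_codon_counts(seqs)
    tab <- setNames(got$count, got$codon)
    expect_equal(tab[names(want)], want)
    expect_equal(sum(got$count), sum(want))
  }
})

test_that("codons containing N are skipped and tallied", {
  tb <- codon_counts("ATGANAAAATAA")
  expect_equal(attr(tb, "skipped"), 1L)
  expect_equal(attr(tb, "n_codons"), 3L)
})

test_that("RSCU follows the definition and conserves family sums", {
  tb <- rscu(codon_counts("ATGAAAAAAAAGTAA"))
  expect_equal(tb$rscu[tb$codon == "AAA"], 4 / 3)
  expect_equal(tb$rscu[tb$codon == "AAG"], 2 / 3)
  expect_equal(tb$rscu[tb$codon == "ATG"], 1)     # single-codon family
  expect_true(is.na(tb$rscu[tb$codon == "TAA"]))  # stops carry no RSCU
  # family-sum conservation on random tables: sum RSCU = family size
  set.seed(42)
  for (trial in 1:10) {
    tb <- rscu(codon_counts(random_cds(sample(50:300, 1))))
    sense <- tb[tb$aa != "*" & !tb$absent, ]
    sums <- tapply(sense$rscu, sense$aa, sum)
    sizes <- tapply(sense$codon, sense$aa, length)
    expect_equal(as.vector(sums), as.vector(sizes, mode = "numeric"),
                 tolerance = 1e-12)
  }
  # zero-count families are flagged absent with RSCU 0
  tb0 <- rscu(codon_counts("ATGAAATAA"))
  expect_true(all(tb0$rscu[tb0$absent] == 0))
  expect_true("TGG" %in% tb0$codon[tb0$absent])
})

test_that("positional GC is computed per codon position, stop excluded", {
  p <- gc_by_position(c(g1 = "ATGAAATAA"))
  expect_equal(p$gc1, 0)     # A,A
  expect_equal(p$gc2, 0)     # T,A
  expect_equal(p$gc3, 0.5)   # G,A
  expect_equal(p$gc12, 0)
  expect_equal(p$n_codons, 2L)
  pg <- gc_by_position("GGGGGGGGGTAA")
  expect_equal(c(pg$gc1, pg$gc2, pg$gc3), c(1, 1, 1))
  expect_equal(p$gc12, (p$gc1 + p$gc2) / 2)
})

test_that("ENC reaches its theoretical limits and never leaves [20, 61]", {
  uniform <- paste(rep(plastomics:::sense_codons(), each = 100),
                   collapse = "")
  expect_equal(enc(uniform)$enc, 61, tolerance = 0.5 / 61)
  one_per_family <- paste(rep(c("TTT", "CTT", "ATT", "GTT", "TCT", "CCT",
                                "ACT", "GCT", "TAT", "CAT", "CAA", "AAT",
                                "AAA", "GAT", "GAA", "TGT", "CGT", "GGT",
                                "ATG", "TGG"), each = 50), collapse = "")
  expect_equal(enc(one_per_family)$enc, 20)
  set.seed(43)
  for (trial in 1:10) {
    e <- enc(random_cds(sample(100:400, 1)))
    if (e$defined) expect_true(e$enc >= 20 && e$enc <= 61)
  }
})

test_that("increasing usage skew within a family never increases ENC", {
  base <- paste(rep(plastomics:::sense_codons(), each = 20), collapse = "")
  skew <- function(k) {
    # move k Lys codons from AAG to AAA, keeping totals fixed
    paste0(base, strrep("AAA", 20 + k), strrep("AAG", 20 - k))
  }
  encs <- vapply(c(0, 5, 10, 15, 20), function(k) enc(skew(k))$enc,
                 numeric(1))
  expect_true(all(diff(encs) <= 1e-9))
})

test_that("the expected-ENC null curve evaluates in closed form", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  s <- seq(0.05, 0.95, by = 0.01)
  expect_equal(s[which.max(enc_expected(s))], 0.5, tolerance = 0.02)
})

test_that("PR2 coordinates restrict to fourfold families", {
  bal <- paste0("GCA", "GCT", "GCG", "GCC")      # Ala with all four thirds
  p <- pr2(bal)
  expect_equal(c(p$x, p$y), c(0.5, 0.5))
  pt <- pr2(paste0("GGT", "CCT", "ACT"))          # only T at third position
  expect_equal(pt$y, 0)
  expect_false(pt$x_defined)
  # enumeration oracle with a hard-coded fourfold list
  fourfold <- c("GC", "GG", "CC", "AC", "GT", "CT", "TC", "CG")
  set.seed(44)
  for (trial in 1:15) {
    s <- random_cds(sample(30:120, 1))
    cods <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 1, 3))
    cods <- cods[substr(cods, 1, 2) %in% fourfold]
    third <- substr(cods, 3, 3)
    want_x <- sum(third == "G") / (sum(third == "G") + sum(third == "C"))
    want_y <- sum(third == "A") / (sum(third == "A") + sum(third == "T"))
    got <- pr2(s)
    if (got$x_defined) expect_equal(got$x, want_x)
    if (got$y_defined) expect_equal(got$y, want_y)
  }
})

test_that("neutrality regression recovers exact and simulated slopes", {
  ident <- data.frame(gc3 = c(0.2, 0.4, 0.6, 0.8),
                      gc12 = c(0.2, 0.4, 0.6, 0.8))
  fit <- suppressWarnings(neutrality_regression(ident))  # exact fit
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)
  expect_error(neutrality_regression(data.frame(gc3 = rep(0.3, 5),
                                                gc12 = runif(5))),
               "constant")
  expect_error(neutrality_regression(ident[1:2, ]), "at least 3")
  set.seed(45)
  b <- 0.35
  for (trial in 1:5) {
    gc3 <- runif(60, 0.1, 0.6)
    gc12 <- 0.2 + b * gc3 + rnorm(60, sd = 0.03)
    f <- neutrality_regression(data.frame(gc3 = gc3, gc12 = gc12))
    se <- summary(f$fit)$coefficients["gc3", "Std. Error"]
    expect_lt(abs(f$slope - b), 3 * se)
  }
})

test_that("codon usage profile assembles per-gene statistics coherently", {
  set.seed(46)
  cds <- data.frame(gene = c("a", "b", "c"),
                    seq = c(random_cds(60), random_cds(80), random_cds(100)),
                    stringsAsFactors = FALSE)
  prof <- codon_usage_profile(cds)
  expect_equal(prof$gene, c("a", "b", "c"))
  expect_equal(prof$n_codons, c(59L, 79L, 99L))  # terminal stop excluded
  expect_true(all(prof$enc >= 20 & prof$enc <= 61))
  expect_equal(prof$gc12, (prof$gc1 + prof$gc2) / 2)
})
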