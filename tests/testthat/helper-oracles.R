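# Independent brute-force oracles used to cross-check the package's
# implementations on small instances. Each oracle is written from the
# definition, not from the implementation's algorithm.

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

# longest exact inverted-repeat pair of a LINEAR sequence by scanning every
# diagonal of the sequence-vs-reverse-complement match matrix; returns the
# best (longest, then smallest start) pair of non-overlapping arms
oracle_longest_ir <- function(s) {
  n <- nchar(s)
  cs <- strsplit(s, "")[[1]]
  cr <- strsplit(oracle_revcomp(s), "")[[1]]
  best <- NULL
  for (d in (-(n - 1)):(n - 1)) {
    i <- max(1, 1 + d):min(n, n + d)      # positions in s
    j <- i - d                             # positions in revcomp(s)
    eq <- cs[i] == cr[j]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (z in which(r$values)) {
      L <- r$lengths[z]
      a1 <- i[ends[z] - L + 1]
      q1 <- j[ends[z] - L + 1]
      b1 <- n - (q1 + L - 1) + 1           # arm B start in s coordinates
      lo <- min(a1, b1); hi <- max(a1, b1)
      if (lo + L - 1 >= hi) next           # overlapping arms
      cand <- c(lo, hi, L)
      if (is.null(best) || L > best[3] ||
          (L == best[3] && lo < best[1])) best <- cand
    }
  }
  best   # c(start1, start2, length) or NULL
}

# exact maximal repeat pairs of one kind by diagonal scanning against the
# transformed sequence; returns data frame sorted like the package output
oracle_dispersed <- function(s, kind, min_length) {
  n <- nchar(s)
  tr <- switch(kind,
    F = s,
    C = chartr("ACGT", "TGCA", s),
    P = oracle_revcomp(s),
    R = paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  cs <- strsplit(s, "")[[1]]
  ct <- strsplit(tr, "")[[1]]
  reversed <- kind %in% c("P", "R")
  out <- list()
  for (d in (-(n - 1)):(n - 1)) {
    i <- max(1, 1 + d):min(n, n + d)
    j <- i - d
    eq <- cs[i] == ct[j]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (z in which(r$values)) {
      L <- r$lengths[z]
      if (L < min_length) next
      p <- i[ends[z] - L + 1]; q <- j[ends[z] - L + 1]
      if (reversed) {
        a2 <- c(n - (q + L - 1) + 1, n - q + 1)
      } else {
        a2 <- c(q, q + L - 1)
      }
      a1 <- c(p, p + L - 1)
      if (kind == "F" && a1[1] == a2[1]) next
      if (a2[1] < a1[1]) { tmp <- a1; a1 <- a2; a2 <- tmp }
      if (a2[1] <= a1[2]) next
      out[[length(out) + 1L]] <- data.frame(
        kind = kind, length = L, start1 = a1[1], end1 = a1[2],
        start2 = a2[1], end2 = a2[2])
    }
  }
  if (!length(out)) return(data.frame(kind = character(0),
                                      length = integer(0),
                                      start1 = integer(0), end1 = integer(0),
                                      start2 = integer(0), end2 = integer(0)))
  res <- unique(do.call(rbind, out))
  res[order(-res$length, res$start1, res$start2), , drop = FALSE]
}

# codon counts by an explicit 3-mer walk with an environment tally
oracle_codon_counts <- function(seqs) {
  env <- new.env()
  for (s in seqs) {
    i <- 1L
    while (i + 2L <= nchar(s)) {
      cod <- substr(s, i, i + 2L)
      if (!grepl("N", cod, fixed = TRUE))
        assign(cod, (if (exists(cod, env)) get(cod, env) else 0L) + 1L, env)
      i <- i + 3L
    }
  }
  tab <- unlist(as.list(env))
  tab[order(names(tab))]
}

# synonymous site count of one codon via Biostrings translation
# (no.init.codon: a lone codon must not be read as an initiator)
oracle_syn_sites <- function(codon) {
  tr <- function(x)
    as.character(Biostrings::translate(
      Biostrings::DNAString(x),
      genetic.code = Biostrings::getGeneticCode("11"),
      no.init.codon = TRUE))
  aa0 <- tr(codon)
  s <- 0
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, p, p)) next
    alt <- codon; substr(alt, p, p) <- b
    if (tr(alt) == aa0) s <- s + 1 / 3
  }
  s
}

# syn/nonsyn differences between two codons by explicit pathway enumeration
oracle_ng86_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  code <- Biostrings::getGeneticCode("11")
  names(code) <- chartr("U", "T", names(code))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- if (length(pos) == 1) list(pos) else if (length(pos) == 2) {
    list(pos, rev(pos))
  } else {
    unlist(lapply(seq_along(pos), function(i)
      lapply(list(pos[-i], rev(pos[-i])), function(rest) c(pos[i], rest))),
      recursive = FALSE)
  }
  paths <- lapply(perms, function(ord) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") blocked <- TRUE
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  })
  m <- do.call(rbind, paths)
  use <- m[, 3] == 0
  if (!any(use)) use <- rep(TRUE, nrow(m))
  c(mean(m[use, 1]), mean(m[use, 2]))
}

# intergenic intervals as the complement of the union of feature extents
oracle_igs_intervals <- function(extents, n) {
  covered <- rep(FALSE, n)
  for (k in seq_len(nrow(extents))) {
    idx <- ((seq.int(extents[k, 1], extents[k, 2]) - 1L) %% n) + 1L
    covered[idx] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gaps <- cbind(start = starts[!r$values], end = ends[!r$values])
  gaps[order(gaps[, 1]), , drop = FALSE]
}

split_codons_oracle <- function(s) {
  substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
}

random_dna_str <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random CDS of n codons with no internal stop and terminal TAA
random_cds <- function(n_codons) {
  sense <- plastomics:::sense_codons()
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# per-site neutral mutation with no constraint at all (stops may arise;
# pair with align_codons(drop_stop_columns = TRUE))
mutate_neutral_free <- function(s, p) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < p)
  ch[hit] <- vapply(hit, function(i)
    sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1), character(1))
  paste(ch, collapse = "")
}

# per-site neutral mutation of a CDS at probability p, never creating a stop
mutate_neutral <- function(s, p) {
  ch <- strsplit(s, "")[[1]]
  gc11 <- genetic_code_11()
  for (i in seq_along(ch)) {
    if (stats::runif(1) >= p) next
    b <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    ci <- (i - 1) %/% 3
    cod <- paste(ch[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
    substr(cod, (i - 1) %% 3 + 1, (i - 1) %% 3 + 1) <- b
    if (gc11[[cod]] != "*") ch[i] <- b
  }
  paste(ch, collapse = "")
}
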