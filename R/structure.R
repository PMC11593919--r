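# Quadripartite structure: inverted-repeat detection, junction accounting,
# regional GC, cross-species gene content.

# integer codes of the first (m) k-mers of a 0..3 base vector; NA where any N
kmer_codes <- function(b, k) {
  m <- length(b) - k + 1L
  if (m < 1L) return(numeric(0))
  codes <- numeric(m)
  for (j in 0:(k - 1L)) codes <- codes * 4 + b[(1L + j):(m + j)]
  codes
}

base_codes <- function(s) {
  v <- utf8ToInt(s)
  out <- rep(NA_real_, length(v))
  out[v == utf8ToInt("A")] <- 0
  out[v == utf8ToInt("C")] <- 1
  out[v == utf8ToInt("G")] <- 2
  out[v == utf8ToInt("T")] <- 3
  out
}

#' Detect the quadripartite partition of a plastome sequence
#'
#' Finds the highest-scoring pair of non-overlapping inverted repeats
#' (longest arm, then fewest mismatches, then smallest start) by exact k-mer
#' seeding between the sequence and its reverse complement followed by
#' maximal extension, and derives the four-region partition. Wrap-around is
#' handled by searching the doubled sequence; the result is normalized to the
#' canonical orientation LSC-IRb-SSC-IRa with LSC the longer single-copy
#' region (ties broken by the lexicographically smaller region sequence).
#'
#' @param sequence DNA string (or a [plastome_record()], whose sequence is
#'   used).
#' @param circular Is the molecule circular? Default `TRUE`.
#' @param min_ir_length Minimum acceptable arm length in bp (default 1000,
#'   appropriate for genuine plastome IRs; lower it for small test fixtures).
#' @param max_mismatch_fraction Mismatch budget per arm as a fraction of arm
#'   length; 0 (default) means exact arms. Seeds are always exact; single
#'   mismatches are bridged greedily while the budget allows.
#' @return Object of class `quadripartite_partition`: region lengths,
#'   `ir_length`, `mismatch_count`, canonical intervals (1-based inclusive),
#'   per-region start coordinates on the input sequence, and genome length.
#' @export
detect_inverted_repeats <- function(sequence, circular = TRUE,
                                    min_ir_length = 1000,
                                    max_mismatch_fraction = 0) {
  if (inherits(sequence, "plastome_record")) {
    circular <- sequence$circular
    sequence <- sequence$sequence
  }
  s <- check_dna(sequence)
  n <- nchar(s)
  S <- if (circular) paste0(s, s) else s
  R <- revcomp(S)
  N2 <- nchar(S)
  k <- max(4L, min(15L, as.integer(min_ir_length)))
  bS <- base_codes(S); bR <- base_codes(R)
  cS <- kmer_codes(bS, k); cR <- kmer_codes(bR, k)
  okS <- which(!is.na(cS)); okR <- which(!is.na(cR))
  common <- intersect(unique(cS[okS]), unique(cR[okR]))
  if (length(common) == 0L)
    stop("no quadripartite structure: no inverted repeat of length >= ",
         min_ir_length, call. = FALSE)
  posS <- okS[cS[okS] %in% common]
  posR <- okR[cR[okR] %in% common]
  byS <- split(posS, cS[posS]); byR <- split(posR, cR[posR])

  covered <- new.env(parent = emptyenv())   # per-diagonal covered intervals
  cand <- list()
  for (code in names(byS)) {
    qs <- byR[[code]]
    if (is.null(qs)) next
    for (p in byS[[code]]) for (q in qs) {
      d <- as.character(p - q)
      iv <- covered[[d]]
      if (!is.null(iv) && any(p >= iv[, 1] & p <= iv[, 2])) next
      m <- extend_match(bS, bR, p, q, k, max_mismatch_fraction)
      covered[[d]] <- rbind(iv, c(m$l, m$r))
      # map the R arm back to S coordinates
      armA <- c(m$l, m$r)
      armB <- c(N2 - m$qr + 1L, N2 - m$ql + 1L)
      cand[[length(cand) + 1L]] <-
        c(a1 = armA[1], a2 = armA[2], b1 = armB[1], b2 = armB[2],
          len = m$r - m$l + 1L, mm = m$mm)
    }
  }
  if (length(cand) == 0L)
    stop("no quadripartite structure found", call. = FALSE)
  cand <- as.data.frame(do.call(rbind, cand))
  # normalize to the circle, order arms, drop self/overlapping pairs
  cand$a1 <- ((cand$a1 - 1L) %% n) + 1L
  cand$b1 <- ((cand$b1 - 1L) %% n) + 1L
  swap <- cand$b1 < cand$a1
  tmp <- cand$a1[swap]; cand$a1[swap] <- cand$b1[swap]; cand$b1[swap] <- tmp
  cand <- cand[cand$len <= n / 2, , drop = FALSE]
  keep <- !duplicated(cand[, c("a1", "b1", "len")])
  cand <- cand[keep, , drop = FALSE]
  # overlap check on the circle: arm A occupies [a1, a1+len), arm B [b1, b1+len)
  gap1 <- cand$b1 - (cand$a1 + cand$len)                  # between A end, B start
  gap2 <- (cand$a1 + n) - (cand$b1 + cand$len)            # wrap side
  ok <- cand$len >= min_ir_length & gap1 >= 0 & gap2 >= 0 &
        cand$a1 != cand$b1
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no quadripartite structure: no non-overlapping inverted-repeat ",
         "pair of length >= ", min_ir_length, call. = FALSE)
  cand <- cand[order(-cand$len, cand$mm, cand$a1), , drop = FALSE]
  best <- cand[1, ]

  build_partition(s, n, circular, best$a1, best$b1, best$len, best$mm)
}

# exact extension (with optional greedy mismatch bridging) of a seed match
# S[p..p+k-1] == R[q..q+k-1]
extend_match <- function(bS, bR, p, q, k, frac) {
  N2 <- length(bS); NR <- length(bR)
  l <- p; ql <- q; r <- p + k - 1L; qr <- q + k - 1L
  mm <- 0L
  repeat {
    ext <- FALSE
    while (r < N2 && qr < NR && !is.na(bS[r + 1L]) &&
           identical(bS[r + 1L], bR[qr + 1L])) {
      r <- r + 1L; qr <- qr + 1L; ext <- TRUE
    }
    while (l > 1L && ql > 1L && !is.na(bS[l - 1L]) &&
           identical(bS[l - 1L], bR[ql - 1L])) {
      l <- l - 1L; ql <- ql - 1L; ext <- TRUE
    }
    if (frac <= 0) break
    budget <- floor(frac * (r - l + 1L)) - mm
    bridged <- FALSE
    if (budget >= 1L && r + 2L <= N2 && qr + 2L <= NR &&
        !is.na(bS[r + 2L]) && identical(bS[r + 2L], bR[qr + 2L])) {
      r <- r + 1L; qr <- qr + 1L; mm <- mm + 1L; bridged <- TRUE
    } else if (budget >= 1L && l - 2L >= 1L && ql - 2L >= 1L &&
               !is.na(bS[l - 2L]) && identical(bS[l - 2L], bR[ql - 2L])) {
      l <- l - 1L; ql <- ql - 1L; mm <- mm + 1L; bridged <- TRUE
    }
    if (!bridged && !ext) break
  }
  list(l = l, r = r, ql = ql, qr = qr, mm = mm)
}

# assemble the partition object from the chosen arm pair
build_partition <- function(s, n, circular, a1, b1, ir_len, mm) {
  a2 <- a1 + ir_len - 1L                 # arm A interval (may exceed n: wrap)
  b2 <- b1 + ir_len - 1L
  gap1_start <- a2 + 1L; gap1_len <- b1 - a2 - 1L            # A -> B
  gap2_start <- b2 + 1L; gap2_len <- (a1 + n) - b2 - 1L      # B -> A (wrap)
  pick_lsc <- if (gap1_len != gap2_len) {
    gap1_len > gap2_len
  } else {
    s1 <- subseq_circular(s, gap1_start, gap1_start + gap1_len - 1L, TRUE)
    s2 <- subseq_circular(s, gap2_start, gap2_start + gap2_len - 1L, TRUE)
    s1 <= s2
  }
  if (pick_lsc) {
    lsc <- c(gap1_start, gap1_len); irb <- c(b1, ir_len)
    ssc <- c(gap2_start, gap2_len); ira <- c(a1 + n, ir_len)
  } else {
    lsc <- c(gap2_start, gap2_len); irb <- c(a1 + n, ir_len)
    ssc <- c(gap1_start + n, gap1_len); ira <- c(b1 + n, ir_len)
  }
  starts <- c(LSC = lsc[1], IRb = irb[1], SSC = ssc[1], IRa = ira[1])
  lens <- c(LSC = lsc[2], IRb = irb[2], SSC = ssc[2], IRa = ira[2])
  starts <- ((starts - 1L) %% n) + 1L
  stopifnot(sum(lens) == n)
  canon_start <- cumsum(c(1, unname(lens[-4])))
  canonical <- cbind(start = canon_start, end = canon_start + unname(lens) - 1)
  rownames(canonical) <- names(lens)
  structure(
    list(lengths = lens, ir_length = as.integer(ir_len),
         mismatch_count = as.integer(mm), starts = starts,
         canonical = canonical, genome_length = n, circular = circular),
    class = "quadripartite_partition"
  )
}

#' Build a partition from known region lengths
#'
#' For records whose IR boundaries are already annotated (or planted by the
#' simulator): the genome is taken to start at the LSC with region order
#' LSC-IRb-SSC-IRa.
#'
#' @param lsc,ir,ssc Region lengths in bp.
#' @param lsc_start 1-based start of the LSC on the record (default 1).
#' @param genome_length Total length; default `lsc + 2 * ir + ssc`.
#' @return A `quadripartite_partition`.
#' @export
partition_from_lengths <- function(lsc, ir, ssc, lsc_start = 1,
                                   genome_length = lsc + 2 * ir + ssc) {
  stopifnot(lsc + 2 * ir + ssc == genome_length)
  n <- genome_length
  starts <- c(LSC = lsc_start, IRb = lsc_start + lsc,
              SSC = lsc_start + lsc + ir, IRa = lsc_start + lsc + ir + ssc)
  starts <- ((starts - 1L) %% n) + 1L
  lens <- c(LSC = lsc, IRb = ir, SSC = ssc, IRa = ir)
  canon_start <- cumsum(c(1, unname(lens[-4])))
  canonical <- cbind(start = canon_start, end = canon_start + unname(lens) - 1)
  rownames(canonical) <- names(lens)
  structure(list(lengths = lens, ir_length = as.integer(ir),
                 mismatch_count = 0L, starts = starts, canonical = canonical,
                 genome_length = n, circular = TRUE),
            class = "quadripartite_partition")
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf("quadripartite partition of %s bp genome\n",
              format(x$genome_length, big.mark = ",")))
  for (r in names(x$lengths)) {
    cat(sprintf("  %-3s %8s bp  (starts at %s)\n", r,
                format(x$lengths[[r]], big.mark = ","),
                format(x$starts[[r]], big.mark = ",")))
  }
  if (x$mismatch_count > 0)
    cat("  IR arms differ at", x$mismatch_count, "positions\n")
  invisible(x)
}

#' Region membership of genome positions
#'
#' @param partition A `quadripartite_partition`.
#' @param pos Vector of 1-based positions on the record the partition was
#'   detected on.
#' @return Character vector in `c("LSC","IRb","SSC","IRa")`.
#' @export
region_of <- function(partition, pos) {
  n <- partition$genome_length
  out <- character(length(pos))
  for (r in names(partition$lengths)) {
    off <- ((pos - partition$starts[[r]]) %% n)
    out[off < partition$lengths[[r]] & out == ""] <- r
  }
  out
}

# 1-based coordinate of the last base of each region (the junction point)
junction_positions <- function(partition) {
  n <- partition$genome_length
  ends <- ((partition$starts + partition$lengths - 2L) %% n) + 1L
  c(JLB = unname(ends["LSC"]), JSB = unname(ends["IRb"]),
    JSA = unname(ends["SSC"]), JLA = unname(ends["IRa"]))
}

#' Junction report: genes flanking the four region boundaries
#'
#' For each junction (JLB = LSC|IRb, JSB = IRb|SSC, JSA = SSC|IRa,
#' JLA = IRa|LSC) reports the nearest feature on each flank with its distance
#' in bp (0 if abutting) and, when a feature crosses the junction, its name
#' with the length on each side.
#'
#' @param record A [plastome_record()].
#' @param partition A `quadripartite_partition` for the record.
#' @param include_pseudo Consider pseudogenes as flanking genes? Default
#'   `FALSE` (functional genes only).
#' @return Data frame with one row per junction: `junction`, `position`
#'   (last base of the upstream region, 1-based), `left_gene`,
#'   `left_distance`, `right_gene`, `right_distance`, `spanning_gene`,
#'   `span_left`, `span_right`.
#' @export
junction_report <- function(record, partition, include_pseudo = FALSE) {
  f <- record$features
  idx <- seq_len(nrow(f))
  if (!include_pseudo) idx <- idx[!f$pseudo[idx]]
  n <- record$length
  ext <- if (length(idx))
    t(vapply(idx, function(i) feature_extent(record, i), numeric(2)))
  else matrix(numeric(0), ncol = 2)
  jpos <- junction_positions(partition)
  rows <- lapply(names(jpos), function(j) {
    b <- jpos[[j]]
    left_g <- NA_character_; left_d <- NA_real_
    right_g <- NA_character_; right_d <- NA_real_
    span_g <- NA_character_; span_l <- NA_real_; span_r <- NA_real_
    for (k in seq_along(idx)) {
      s0 <- ext[k, 1]; e0 <- ext[k, 2]
      for (shift in c(-n, 0, n)) {
        s <- s0 + shift; e <- e0 + shift
        if (s <= b && b < e) {                       # spans the junction
          sl <- b - s + 1; sr <- e - b
          if (is.na(span_g) || sl + sr > span_l + span_r) {
            span_g <- f$name[idx[k]]; span_l <- sl; span_r <- sr
          }
        }
        if (e <= b) {
          d <- b - e
          if (is.na(left_d) || d < left_d) { left_d <- d; left_g <- f$name[idx[k]] }
        }
        if (s >= b + 1) {
          d <- s - b - 1
          if (is.na(right_d) || d < right_d) { right_d <- d; right_g <- f$name[idx[k]] }
        }
      }
    }
    data.frame(junction = j, position = b,
               left_gene = if (is.na(left_g)) "none" else left_g,
               left_distance = left_d,
               right_gene = if (is.na(right_g)) "none" else right_g,
               right_distance = right_d,
               spanning_gene = if (is.na(span_g)) "none" else span_g,
               span_left = span_l, span_right = span_r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regional GC content
#'
#' GC fraction (G+C over A+C+G+T, N excluded from both numerator and
#' denominator) for each of the four regions and the whole genome.
#'
#' @param record A [plastome_record()].
#' @param partition A `quadripartite_partition`.
#' @return Named numeric vector `overall, LSC, IRb, SSC, IRa` of fractions in
#'   `[0, 1]`; `NA` for a zero-length region.
#' @export
regional_gc <- function(record, partition) {
  s <- record$sequence
  out <- c(overall = gc_fraction(s))
  for (r in names(partition$lengths)) {
    len <- partition$lengths[[r]]
    out[[r]] <- if (len == 0) NA_real_ else
      gc_fraction(subseq_circular(s, partition$starts[[r]],
                                  partition$starts[[r]] + len - 1L,
                                  record$circular))
  }
  out
}

#' Gene presence / pseudogenization / loss matrix across records
#'
#' @param records List of [plastome_record()] objects.
#' @param gene_universe Gene symbols to report; default the union of names
#'   across records.
#' @return Character matrix (class `gene_presence_matrix`) with rows = record
#'   ids, columns = genes, cells in `c("present","pseudo","lost")`. A gene is
#'   `pseudo` if any copy is flagged pseudo, else `present` if any functional
#'   copy exists, else `lost`.
#' @export
gene_content_matrix <- function(records, gene_universe = NULL) {
  stopifnot(length(records) >= 1)
  if (is.null(gene_universe))
    gene_universe <- sort(unique(unlist(lapply(records,
                                               function(r) r$features$name))))
  m <- matrix("lost", nrow = length(records), ncol = length(gene_universe),
              dimnames = list(vapply(records, `[[`, "", "id"), gene_universe))
  for (i in seq_along(records)) {
    f <- records[[i]]$features
    for (g in gene_universe) {
      rows <- f[f$name == g, , drop = FALSE]
      if (nrow(rows) == 0L) next
      m[i, g] <- if (any(rows$pseudo)) "pseudo" else "present"
    }
  }
  class(m) <- c("gene_presence_matrix", class(m))
  m
}
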