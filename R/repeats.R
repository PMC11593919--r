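# Repeat detection: perfect microsatellites (MISA semantics) and dispersed
# repeats of the four REPuter classes (forward, reverse, palindromic,
# complementary) with a Hamming mismatch budget.

#' Find simple sequence repeats (microsatellites)
#'
#' Reports every maximal perfect tandem run of a 1-6 bp unit meeting its
#' per-unit-length minimum copy number. A run is reported at its smallest
#' primitive unit only (poly-A is a mononucleotide repeat, never "AA"), which
#' also suppresses duplicate reports of one run at multiple unit lengths.
#'
#' @param sequence DNA string or [plastome_record()].
#' @param thresholds Named integer vector: minimum copy number per unit
#'   length 1-6. Default `c(10, 5, 4, 3, 3, 3)` (standard plastome MISA
#'   settings).
#' @param circular Scan across the origin (doubled-sequence scan with reports
#'   deduplicated modulo length)? Default `FALSE`: linear coordinates as
#'   deposited.
#' @return Data frame: `motif` (unit as found), `canonical_class`,
#'   `unit_length`, `repeat_count`, `start`, `end` (1-based inclusive;
#'   `end` exceeds the sequence length for an origin-spanning run).
#' @export
find_ssrs <- function(sequence,
                      thresholds = c(`1` = 10, `2` = 5, `3` = 4,
                                     `4` = 3, `5` = 3, `6` = 3),
                      circular = FALSE) {
  if (inherits(sequence, "plastome_record")) sequence <- sequence$sequence
  s <- check_dna(sequence)
  n <- nchar(s)
  scan <- if (circular) paste0(s, s) else s
  ch <- strsplit(scan, "")[[1]]
  m <- length(ch)
  out <- list()
  for (u in as.integer(names(thresholds))) {
    thr <- thresholds[[as.character(u)]]
    if (m < u * 2L) next
    eq <- ch[seq_len(m - u)] == ch[(u + 1L):m] & ch[seq_len(m - u)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (z in which(r$values)) {
      L <- r$lengths[z]
      copies <- (L + u) %/% u
      if (copies < thr) next
      i <- starts[z]
      motif <- substr(scan, i, i + u - 1L)
      if (!is_primitive_motif(motif)) next
      ssr_len <- copies * u
      if (circular && ssr_len > n) { copies <- n %/% u; ssr_len <- copies * u }
      if (copies < thr) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_length = u, repeat_count = copies,
        start = i, end = i + ssr_len - 1L, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(motif = character(0), unit_length = integer(0),
               repeat_count = integer(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  if (circular && nrow(res) > 0) {
    res <- res[res$start <= n, , drop = FALSE]
    # a run seen once in [1, n] and again shifted by n is the same run
    key <- paste(res$motif, ((res$start - 1L) %% n), res$repeat_count)
    res <- res[!duplicated(key), , drop = FALSE]
  }
  if (nrow(res) > 0) {
    res$canonical_class <- vapply(res$motif, canonical_motif, character(1),
                                  USE.NAMES = FALSE)
    res <- res[order(res$start), , drop = FALSE]
    rownames(res) <- NULL
    res <- res[, c("motif", "canonical_class", "unit_length", "repeat_count",
                   "start", "end")]
  } else res$canonical_class <- character(0)
  res
}

# TRUE if the motif is not a whole-number repetition of a shorter unit
is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (identical(strrep(substr(motif, 1L, d), u %/% d), motif)) return(FALSE)
  }
  TRUE
}

#' Canonical SSR motif class
#'
#' MISA-style grouping: the lexicographically smallest rotation of the motif
#' and of its reverse complement, joined in sorted order as `"X/Y"`. Both
#' strands and all phases of one repeat therefore share a class (e.g. `"T"`,
#' `"A"` are both `"A/T"`; `"TTA"` is `"AAT/ATT"`).
#'
#' @param motif Repeat unit, 1-6 bp over `A,C,G,T`.
#' @return Class label string.
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]{1,6}$", motif))
    stop("motif must be 1-6 bp over A,C,G,T: ", motif, call. = FALSE)
  a <- min_rotation(motif)
  b <- min_rotation(revcomp(motif))
  paste(sort(c(a, b)), collapse = "/")
}

min_rotation <- function(x) {
  u <- nchar(x)
  d <- paste0(x, x)
  min(substring(d, seq_len(u), seq_len(u) + u - 1L))
}

#' Classify SSR genomic location
#'
#' Assigns each SSR a region (by midpoint membership in the quadripartite
#' partition) and a context: `exon` if the midpoint lies inside a feature
#' part, `intron` if inside a feature's inter-part gap, `IGS` otherwise.
#'
#' @param ssrs SSR data frame from [find_ssrs()].
#' @param record The [plastome_record()] the SSRs were found on.
#' @param partition A `quadripartite_partition` for the record.
#' @return `ssrs` with `region` and `context` columns added.
#' @export
classify_ssr_location <- function(ssrs, record, partition) {
  n <- record$length
  mid <- ((floor((ssrs$start + ssrs$end) / 2) - 1L) %% n) + 1L
  ssrs$region <- region_of(partition, mid)
  f <- record$features
  ctx <- rep("IGS", length(mid))
  for (i in seq_len(nrow(f))) {
    p <- f$parts[[i]]
    for (r in seq_len(nrow(p)))
      ctx[mid >= p[r, 1] & mid <= p[r, 2]] <- "exon"
  }
  # intron: inside a feature extent but not in any part
  for (i in seq_len(nrow(f))) {
    ext <- feature_extent(record, i)
    inside <- (mid >= ext[1] & mid <= ext[2]) |
      (mid + n >= ext[1] & mid + n <= ext[2])
    ctx[inside & ctx == "IGS"] <- "intron"
  }
  ssrs$context <- ctx
  ssrs
}

#' Find dispersed repeats (forward / reverse / palindromic / complementary)
#'
#' Maximal repeat pairs of the four classes with Hamming distance at most
#' `max_mismatch` between the transformed copies, found by exact k-mer
#' seeding against the transformed sequence and greedy extension within the
#' mismatch budget. Pairs contained within a longer reported pair of the same
#' kind are suppressed; results are sorted by length descending (ties by
#' smaller start) and truncated at `max_reported`.
#'
#' @param sequence DNA string or [plastome_record()].
#' @param min_length Minimum arm length in bp (default 30).
#' @param max_mismatch Hamming distance budget (default 3).
#' @param max_reported Maximum number of pairs returned (default 5000).
#' @param kinds Subset of `c("F","R","P","C")` to search.
#' @param mask_partition Optional `quadripartite_partition`: suppress the
#'   genome-scale IRb/IRa self-match (pairs whose arms are essentially
#'   coextensive with the two IR regions), so the output lists dispersed
#'   repeats rather than the quadripartite structure itself.
#' @return Data frame: `kind`, `length`, `start1`, `end1`, `start2`, `end2`
#'   (1-based inclusive, arm 1 upstream), `mismatches`.
#' @export
find_dispersed_repeats <- function(sequence, min_length = 30,
                                   max_mismatch = 3, max_reported = 5000,
                                   kinds = c("F", "R", "P", "C"),
                                   mask_partition = NULL) {
  if (inherits(sequence, "plastome_record")) sequence <- sequence$sequence
  s <- check_dna(sequence)
  n <- nchar(s)
  k <- max(3L, min(12L, (min_length - max_mismatch) %/% (max_mismatch + 1L)))
  bS <- base_codes(s)
  rows <- list()
  for (kind in kinds) {
    tr <- switch(kind,
      F = list(seq = s, reversed = FALSE),
      C = list(seq = complement_seq(s), reversed = FALSE),
      P = list(seq = revcomp(s), reversed = TRUE),
      R = list(seq = reverse_seq(s), reversed = TRUE))
    bT <- base_codes(tr$seq)
    cS <- kmer_codes(bS, k); cT <- kmer_codes(bT, k)
    okS <- which(!is.na(cS)); okT <- which(!is.na(cT))
    common <- intersect(unique(cS[okS]), unique(cT[okT]))
    if (length(common) == 0L) next
    posS <- okS[cS[okS] %in% common]
    posT <- okT[cT[okT] %in% common]
    byS <- split(posS, cS[posS]); byT <- split(posT, cT[posT])
    covered <- new.env(parent = emptyenv())
    for (code in names(byS)) {
      qs <- byT[[code]]
      if (is.null(qs)) next
      for (p in byS[[code]]) for (q in qs) {
        if (kind == "F" && p == q) next
        d <- as.character(p - q)
        iv <- covered[[d]]
        if (!is.null(iv) && any(p >= iv[, 1] & p <= iv[, 2])) next
        e <- extend_hamming(bS, bT, p, q, k, max_mismatch)
        covered[[d]] <- rbind(iv, c(e$l, e$r))
        L <- e$r - e$l + 1L
        if (L < min_length) next
        if (tr$reversed) {
          a2 <- c(n - e$qr + 1L, n - e$ql + 1L)
        } else {
          a2 <- c(e$ql, e$qr)
        }
        a1 <- c(e$l, e$r)
        if (a2[1] < a1[1]) { tmp <- a1; a1 <- a2; a2 <- tmp }
        if (a2[1] <= a1[2]) next                      # overlapping arms
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, length = L, start1 = a1[1], end1 = a1[2],
          start2 = a2[1], end2 = a2[2], mismatches = e$mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), length = integer(0), start1 = integer(0),
               end1 = integer(0), start2 = integer(0), end2 = integer(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  if (nrow(res) > 0) {
    res <- res[!duplicated(res[, c("kind", "start1", "start2", "length")]), ,
               drop = FALSE]
    res <- res[order(-res$length, res$start1, res$start2), , drop = FALSE]
    res <- suppress_contained(res)
    if (!is.null(mask_partition)) res <- mask_ir_pair(res, mask_partition)
    if (nrow(res) > max_reported) res <- res[seq_len(max_reported), ,
                                             drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

# maximal Hamming extension of an exact seed along its diagonal: the budget
# is split between the two directions so total length is maximized, and the
# extension always ends on a matching position
extend_hamming <- function(bS, bT, p, q, k, budget) {
  nS <- length(bS); nT <- length(bT)
  # gain[j + 1] = farthest advance in one direction using <= j mismatches,
  # ending on a match
  scan_dir <- function(s0, t0, step) {
    gain <- integer(budget + 1L)
    mm <- 0L; adv <- 0L
    i <- s0; j <- t0
    repeat {
      i <- i + step; j <- j + step
      if (i < 1L || i > nS || j < 1L || j > nT) break
      if (is.na(bS[i]) || is.na(bT[j])) break
      adv <- adv + 1L
      if (bS[i] == bT[j]) {
        gain[mm + 1L] <- adv
      } else {
        mm <- mm + 1L
        if (mm > budget) break
      }
    }
    cummax(gain)
  }
  gl <- scan_dir(p, q, -1L)
  gr <- scan_dir(p + k - 1L, q + k - 1L, 1L)
  tot <- vapply(0:budget, function(j) gl[j + 1L] + gr[budget - j + 1L],
                integer(1))
  jl <- which.max(tot) - 1L
  l <- p - gl[jl + 1L]; ql <- q - gl[jl + 1L]
  r <- p + k - 1L + gr[budget - jl + 1L]
  qr <- q + k - 1L + gr[budget - jl + 1L]
  mm <- sum(bS[l:r] != bT[ql:qr])
  list(l = l, r = r, ql = ql, qr = qr, mm = mm)
}

# drop pairs whose arms both lie within a longer pair's arms (same kind);
# input sorted by length descending
suppress_contained <- function(res) {
  keep <- rep(TRUE, nrow(res))
  for (j in seq_len(nrow(res))) {
    if (!keep[j]) next
    for (i in seq_len(j - 1L)) {
      if (!keep[i] || res$kind[i] != res$kind[j]) next
      if (res$start1[i] <= res$start1[j] && res$end1[j] <= res$end1[i] &&
          res$start2[i] <= res$start2[j] && res$end2[j] <= res$end2[i]) {
        keep[j] <- FALSE; break
      }
    }
  }
  res[keep, , drop = FALSE]
}

# drop pairs essentially coextensive with the IRb/IRa pair
mask_ir_pair <- function(res, partition) {
  irs <- list(c(partition$starts[["IRb"]],
                partition$starts[["IRb"]] + partition$lengths[["IRb"]] - 1),
              c(partition$starts[["IRa"]],
                partition$starts[["IRa"]] + partition$lengths[["IRa"]] - 1))
  covers <- function(s, e, iv) {
    ov <- max(0, min(e, iv[2]) - max(s, iv[1]) + 1)
    ov / (e - s + 1) >= 0.9 && (e - s + 1) >= 0.5 * partition$ir_length
  }
  drop <- vapply(seq_len(nrow(res)), function(i) {
    any(vapply(irs, function(u) covers(res$start1[i], res$end1[i], u),
               logical(1))) &&
    any(vapply(irs, function(u) covers(res$start2[i], res$end2[i], u),
               logical(1)))
  }, logical(1))
  res[!drop, , drop = FALSE]
}

#' Verify a dispersed repeat against its defining transform
#'
#' @param sequence The DNA string the repeat was reported on.
#' @param kind `"F"`, `"R"`, `"P"` or `"C"`.
#' @param start1,end1,start2,end2 Arm coordinates (1-based inclusive).
#' @return Hamming distance between arm 2 and the transformed arm 1.
#' @export
verify_repeat <- function(sequence, kind, start1, end1, start2, end2) {
  a1 <- substr(sequence, start1, end1)
  a2 <- substr(sequence, start2, end2)
  t1 <- switch(kind, F = a1, R = reverse_seq(a1), P = revcomp(a1),
               C = complement_seq(a1))
  stopifnot(nchar(t1) == nchar(a2))
  sum(strsplit(t1, "")[[1]] != strsplit(a2, "")[[1]])
}
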