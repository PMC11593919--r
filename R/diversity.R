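# Per-locus nucleotide diversity and hypervariable-region calling.

#' Nucleotide diversity of an alignment
#'
#' Average over all sequence pairs of the proportion of differing sites.
#' Under complete deletion (default, the DnaSP convention) a column is usable
#' only if no row carries a gap or N; under pairwise deletion usable sites
#' are determined per pair.
#'
#' @param alignment Character vector (>= 2 rows) of equal-length aligned
#'   sequences over `A,C,G,T,N,-`, or a character matrix of single
#'   characters.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return List with `pi`, `usable_sites` (complete deletion; `NA` under
#'   pairwise), `n_sequences`, and `defined`.
#' @export
nucleotide_diversity <- function(alignment,
                                 deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- as_alignment_matrix(alignment)
  nr <- nrow(m)
  if (nr < 2L) stop("alignment needs at least 2 sequences", call. = FALSE)
  bad <- m == "-" | m == "N"
  pairs <- utils::combn(nr, 2L)
  if (deletion == "complete") {
    use <- !apply(bad, 2L, any)
    usable <- sum(use)
    if (usable == 0L)
      return(list(pi = NA_real_, usable_sites = 0L, n_sequences = nr,
                  defined = FALSE))
    mm <- m[, use, drop = FALSE]
    d <- apply(pairs, 2L, function(p) sum(mm[p[1], ] != mm[p[2], ]) / usable)
    list(pi = mean(d), usable_sites = usable, n_sequences = nr,
         defined = TRUE)
  } else {
    d <- apply(pairs, 2L, function(p) {
      ok <- !(bad[p[1], ] | bad[p[2], ])
      if (!any(ok)) return(NA_real_)
      sum(m[p[1], ok] != m[p[2], ok]) / sum(ok)
    })
    if (all(is.na(d)))
      return(list(pi = NA_real_, usable_sites = NA_integer_,
                  n_sequences = nr, defined = FALSE))
    list(pi = mean(d, na.rm = TRUE), usable_sites = NA_integer_,
         n_sequences = nr, defined = TRUE)
  }
}

as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  alignment <- toupper(alignment)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  do.call(rbind, strsplit(alignment, ""))
}

#' Naive center-star multiple alignment
#'
#' Lightweight built-in aligner for tests and synthetic data: every sequence
#' is globally aligned to the first with [Biostrings::pairwiseAlignment()]
#' and insertions are merged into a common coordinate frame. Adequate for
#' closely related plastome loci; production analyses may substitute any
#' external multiple aligner via the `aligner` hook of [shared_locus_pi()].
#'
#' @param seqs Character vector of >= 2 DNA sequences.
#' @return Character vector of equal-length aligned sequences.
#' @export
align_loci_naive <- function(seqs) {
  stopifnot(length(seqs) >= 2L)
  seqs <- toupper(seqs)
  # equal lengths: treated as positionally homologous (no indel model)
  if (length(unique(nchar(seqs))) == 1L) return(seqs)
  center <- seqs[1]
  L <- nchar(center)
  # per sequence: char aligned to each center position, plus the insertion
  # string preceding each center position (slot L+1 = trailing insertions)
  decomp <- lapply(seqs[-1], function(s) {
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(s),
                                        Biostrings::DNAString(center),
                                        type = "global")
    patt <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    subj <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    base <- character(L)
    ins <- rep("", L + 1L)
    pos <- 0L
    for (j in seq_along(subj)) {
      if (subj[j] == "-") {
        ins[pos + 1L] <- paste0(ins[pos + 1L], patt[j])
      } else {
        pos <- pos + 1L
        base[pos] <- patt[j]
      }
    }
    list(base = base, ins = ins)
  })
  width <- rep(0L, L + 1L)
  for (d in decomp) width <- pmax(width, nchar(d$ins))
  render <- function(base, ins) {
    pieces <- character(0)
    for (p in seq_len(L + 1L)) {
      pieces <- c(pieces,
                  paste0(ins[p], strrep("-", width[p] - nchar(ins[p]))))
      if (p <= L) pieces <- c(pieces, base[p])
    }
    paste(pieces, collapse = "")
  }
  center_row <- render(strsplit(center, "")[[1]], rep("", L + 1L))
  rows <- vapply(decomp, function(d) render(d$base, d$ins), character(1))
  res <- c(center_row, rows)
  names(res) <- names(seqs)
  res
}

#' Nucleotide diversity of loci shared across records
#'
#' Matches gene and IGS loci by name across all records (intersection),
#' aligns each shared locus with the supplied hook, computes pi and flags
#' hypervariable loci above the threshold.
#'
#' @param records List of >= 2 [plastome_record()] objects.
#' @param aligner Function `character vector -> aligned character vector`;
#'   default [align_loci_naive()].
#' @param threshold Hypervariability threshold on pi (default 0.07).
#' @param deletion Site-deletion rule, see [nucleotide_diversity()].
#' @return Data frame: `locus`, `kind`, `usable_sites`, `pi`,
#'   `hypervariable`, sorted by decreasing pi. Loci absent from any record
#'   are excluded (a message reports how many).
#' @export
shared_locus_pi <- function(records, aligner = align_loci_naive,
                            threshold = 0.07,
                            deletion = "complete") {
  stopifnot(length(records) >= 2L)
  loci <- lapply(records, extract_loci)
  shared <- Reduce(intersect, lapply(loci, function(l) l$name))
  dropped <- length(unique(unlist(lapply(loci, function(l) l$name)))) -
    length(shared)
  if (dropped > 0)
    message(dropped, " loci absent from at least one record were excluded")
  if (length(shared) == 0L) {
    warning("no loci shared by all records", call. = FALSE)
    return(data.frame(locus = character(0), kind = character(0),
                      usable_sites = integer(0), pi = numeric(0),
                      hypervariable = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(shared, function(nm) {
    seqs <- vapply(loci, function(l) l$seq[match(nm, l$name)], character(1))
    kind <- loci[[1]]$kind[match(nm, loci[[1]]$name)]
    aln <- aligner(seqs)
    pv <- nucleotide_diversity(aln, deletion = deletion)
    data.frame(locus = nm, kind = kind, usable_sites = pv$usable_sites,
               pi = pv$pi, hypervariable = isTRUE(pv$pi > threshold),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-ifelse(is.na(res$pi), -1, res$pi)), , drop = FALSE]
  rownames(res) <- NULL
  res
}
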