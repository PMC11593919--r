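# Feature extraction: coding sequences, gene/IGS loci, gene inventory.

#' Extract coding sequences from a plastome record
#'
#' Splices every functional CDS feature (multi-part features joined in order,
#' minus strand reverse-complemented) and applies the plastid validity checks:
#' length divisible by three and no internal stop under translation table 11.
#' Invalid CDSs are excluded with a warning and collected in the `rejects`
#' attribute.
#'
#' @param record A [plastome_record()].
#' @param min_length Minimum spliced length in bp (default 0).
#' @param dedupe_ir_copies If `TRUE` (default) only the first genome-order copy
#'   of a gene duplicated in the inverted repeats is returned.
#' @return Data frame with columns `gene`, `seq`, `source_record`, ordered by
#'   genome position; attribute `rejects` lists excluded CDS names and reasons.
#' @export
extract_cds <- function(record, min_length = 0, dedupe_ir_copies = TRUE) {
  f <- record$features
  idx <- which(f$kind == "CDS" & !f$pseudo)
  if (dedupe_ir_copies) idx <- idx[f$copy_index[idx] == 1L]
  # genome order
  if (length(idx)) {
    starts <- vapply(idx, function(i) min(f$parts[[i]][, 1]), numeric(1))
    idx <- idx[order(starts)]
  }
  out <- list(); rejects <- list()
  for (i in idx) {
    s <- splice_feature(record, i)
    if (nchar(s) < min_length) next
    if (nchar(s) %% 3 != 0 && !f$partial[i]) {
      warning(sprintf("CDS '%s' length %d not divisible by 3; excluded",
                      f$name[i], nchar(s)), call. = FALSE)
      rejects[[length(rejects) + 1L]] <-
        data.frame(gene = f$name[i], reason = "length not divisible by 3")
      next
    }
    if (nchar(s) %% 3 == 0) {
      aa <- translate_cds(s)
      body <- substr(aa, 1L, nchar(aa) - 1L)
      if (grepl("*", body, fixed = TRUE) && !f$partial[i]) {
        warning(sprintf("CDS '%s' has an internal stop codon; excluded",
                        f$name[i]), call. = FALSE)
        rejects[[length(rejects) + 1L]] <-
          data.frame(gene = f$name[i], reason = "internal stop codon")
        next
      }
    }
    out[[length(out) + 1L]] <- data.frame(gene = f$name[i], seq = s,
                                          source_record = record$id,
                                          stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(0), seq = character(0),
               source_record = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "rejects") <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(gene = character(0), reason = character(0))
  res
}

#' Extract gene and intergenic-spacer loci
#'
#' Yields one locus per feature name (the full genomic extent, introns
#' included; for IR-duplicated genes the first copy) and one IGS locus per
#' positive gap between consecutive features in genome order, named
#' `"geneA-geneB"` from the flanking symbols. Overlapping adjacencies emit no
#' IGS.
#'
#' @param record A [plastome_record()].
#' @param include_pseudo Include pseudogenes as gene loci (default `TRUE`,
#'   since spacers are bounded by annotated features regardless of function).
#' @return Data frame with columns `name`, `kind` (`"gene"`/`"IGS"`), `seq`,
#'   `start`, `end` (1-based inclusive, end may exceed the record length for
#'   an origin-spanning locus).
#' @export
extract_loci <- function(record, include_pseudo = TRUE) {
  f <- record$features
  idx <- seq_len(nrow(f))
  if (!include_pseudo) idx <- idx[!f$pseudo[idx]]
  if (length(idx) == 0L)
    return(data.frame(name = character(0), kind = character(0),
                      seq = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  ext <- t(vapply(idx, function(i) feature_extent(record, i), numeric(2)))
  ord <- order(ext[, 1])
  idx <- idx[ord]; ext <- ext[ord, , drop = FALSE]
  n <- record$length

  rows <- list()
  for (k in seq_along(idx)) {
    i <- idx[k]
    rows[[length(rows) + 1L]] <- data.frame(
      name = f$name[i], kind = "gene",
      seq = subseq_circular(record$sequence, ext[k, 1], ext[k, 2],
                            record$circular),
      start = as.integer(ext[k, 1]), end = as.integer(ext[k, 2]),
      stringsAsFactors = FALSE)
  }
  # spacers between the feature cover and the next feature in genome order
  # (circular closure included); overlapping features emit no spacer
  m <- length(idx)
  cur_end <- ext[1, 2]; cur_i <- idx[1]
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    if (k == m && !record$circular) break
    gap_start <- cur_end + 1
    gap_end <- if (k == m) ext[1, 1] + n - 1 else ext[k2, 1] - 1
    if (gap_end >= gap_start) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(f$name[cur_i], "-", f$name[idx[k2]]), kind = "IGS",
        seq = subseq_circular(record$sequence, gap_start, gap_end,
                              record$circular),
        start = as.integer(gap_start), end = as.integer(gap_end),
        stringsAsFactors = FALSE)
    }
    if (k < m && ext[k2, 2] > cur_end) { cur_end <- ext[k2, 2]; cur_i <- idx[k2] }
  }
  res <- do.call(rbind, rows)
  # one locus per gene name: keep first copy of IR duplicates
  res <- res[!(res$kind == "gene" & duplicated(res$name)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene inventory summary
#'
#' Counts unique gene names, IR-duplicated genes, the per-copy total, and
#' per-kind tallies. Pseudogenes are reported separately and excluded from the
#' functional totals; `total_with_pseudo` gives the alternative convention.
#'
#' @param record A [plastome_record()].
#' @return List with `unique_genes`, `duplicated_genes`, `total_genes`,
#'   `by_kind`, `pseudo_genes`, `total_with_pseudo`.
#' @export
count_genes <- function(record) {
  f <- record$features
  fun <- f[!f$pseudo, , drop = FALSE]
  pse <- f[f$pseudo, , drop = FALSE]
  copies <- table(fun$name)
  by_kind <- vapply(c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA"),
                    function(k) length(unique(fun$name[fun$kind == k])),
                    integer(1))
  list(
    unique_genes = length(copies),
    duplicated_genes = sum(copies > 1L),
    total_genes = as.integer(sum(copies)),
    by_kind = by_kind,
    pseudo_genes = unique(pse$name),
    total_with_pseudo = as.integer(sum(copies) + length(unique(pse$name)))
  )
}
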