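# The central container: a circular annotated plastome.

#' Construct a plastome record
#'
#' A `plastome_record` holds one (usually circular) chloroplast genome:
#' an upper-case DNA sequence over \code{A,C,G,T,N} plus an ordered feature
#' table of gene loci (CDS, tRNA, rRNA). Coordinates are 1-based inclusive;
#' a multi-part feature (introns, or a feature spanning the origin of a
#' circular molecule) stores one interval per part in genomic join order.
#'
#' @param id Record identifier (accession-like string).
#' @param sequence DNA string; characters other than \code{A,C,G,T,N} are an
#'   error. Lower case is accepted and upper-cased.
#' @param circular Logical; is the molecule circular?
#' @param features Feature table as built by [gene_feature()]/[feature_table()],
#'   or `NULL` for none.
#' @return Object of class `plastome_record` with elements `id`, `sequence`,
#'   `length`, `circular` and `features` (a data frame with columns `name`,
#'   `kind`, `strand`, `pseudo`, `partial`, `copy_index` and a list column
#'   `parts` of two-column start/end matrices).
#' @export
plastome_record <- function(id, sequence, circular = TRUE, features = NULL) {
  sequence <- check_dna(sequence, sprintf("record '%s'", id))
  n <- nchar(sequence)
  if (n == 0L) stop("record sequence must be non-empty", call. = FALSE)
  if (is.null(features)) features <- feature_table()
  stopifnot(is.data.frame(features))
  # validate intervals
  for (i in seq_len(nrow(features))) {
    p <- features$parts[[i]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 1L)
      stop("feature '", features$name[i], "': parts must be a start/end matrix",
           call. = FALSE)
    if (any(p < 1L) || any(p > n))
      stop("feature '", features$name[i],
           "' has an interval outside the sequence [1, ", n, "]", call. = FALSE)
    if (any(p[, 1] > p[, 2]))
      stop("feature '", features$name[i], "': part start exceeds end",
           call. = FALSE)
  }
  if (nrow(features) > 0) {       # normalize to genome order
    starts <- vapply(features$parts, function(p) min(p[, 1]), numeric(1))
    features <- features[order(starts), , drop = FALSE]
    rownames(features) <- NULL
  }
  features <- assign_copy_index(features)
  structure(
    list(id = id, sequence = sequence, length = n, circular = circular,
         features = features),
    class = "plastome_record"
  )
}

#' Describe one gene feature
#'
#' @param name Gene symbol, e.g. `"rbcL"` or `"trnH-GUG"`.
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @param start,end 1-based inclusive interval (single-part features). For
#'   multi-part features pass `parts` instead.
#' @param strand `"+"` or `"-"`.
#' @param parts Optional two-column matrix of start/end rows in join order.
#' @param pseudo Logical pseudogene flag (trusted as annotated).
#' @param partial Logical; CDS truncated at a record edge (relaxes the
#'   divisible-by-three check).
#' @return One-row feature data frame; bind rows with [feature_table()].
#' @export
gene_feature <- function(name, kind, start = NULL, end = NULL, strand = "+",
                         parts = NULL, pseudo = FALSE, partial = FALSE) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA"))
  stopifnot(strand %in% c("+", "-"))
  if (is.null(parts)) {
    stopifnot(!is.null(start), !is.null(end))
    parts <- cbind(start = as.integer(start), end = as.integer(end))
  } else {
    parts <- matrix(as.integer(parts), ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
  }
  df <- data.frame(name = name, kind = kind, strand = strand,
                   pseudo = pseudo, partial = partial, copy_index = 1L,
                   stringsAsFactors = FALSE)
  df$parts <- list(parts)
  df
}

#' Combine gene features into a feature table
#'
#' @param ... One-row feature frames from [gene_feature()].
#' @return Feature data frame (possibly empty).
#' @export
feature_table <- function(...) {
  fs <- list(...)
  if (length(fs) == 0L) {
    df <- data.frame(name = character(0), kind = character(0),
                     strand = character(0), pseudo = logical(0),
                     partial = logical(0), copy_index = integer(0),
                     stringsAsFactors = FALSE)
    df$parts <- list()
    return(df)
  }
  do.call(rbind, fs)
}

# number duplicate gene copies (IR duplicates) by genome order
assign_copy_index <- function(features) {
  if (nrow(features) == 0L) return(features)
  starts <- vapply(features$parts, function(p) min(p[, 1]), numeric(1))
  ord <- order(starts)
  idx <- integer(nrow(features))
  idx[ord] <- stats::ave(seq_along(ord), features$name[ord],
                         FUN = seq_along)
  features$copy_index <- idx
  features
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("plastome_record '%s': %s bp, %s, %d features\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features) > 0) {
    kinds <- table(x$features$kind)
    cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# circular substring, 1-based inclusive; end may exceed length (wraps)
subseq_circular <- function(seq, start, end, circular = TRUE) {
  n <- nchar(seq)
  if (end <= n && start >= 1L) return(substr(seq, start, end))
  if (!circular) stop("interval outside a linear sequence", call. = FALSE)
  # normalize start into [1, n]
  start <- ((start - 1L) %% n) + 1L
  len <- end - start + 1L
  if (len <= 0L) stop("empty circular interval", call. = FALSE)
  doubled <- paste0(seq, seq)
  substr(doubled, start, start + len - 1L)
}

# genomic extent of a feature in unwrapped coordinates: c(start, end) where
# end may exceed record length for origin-spanning features
feature_extent <- function(record, i) {
  p <- record$features$parts[[i]]
  n <- record$length
  start <- p[1, 1]
  hi <- p[1, 2]
  if (nrow(p) > 1) {
    for (r in 2:nrow(p)) {
      s <- p[r, 1]; e <- p[r, 2]
      while (s < start) { s <- s + n; e <- e + n }  # unwrap across origin
      hi <- max(hi, e)
    }
  }
  c(start = start, end = hi)
}

# spliced, strand-oriented sequence of feature i
splice_feature <- function(record, i) {
  p <- record$features$parts[[i]]
  pieces <- vapply(seq_len(nrow(p)), function(r) {
    subseq_circular(record$sequence, p[r, 1], p[r, 2], record$circular)
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (record$features$strand[i] == "-") s <- revcomp(s) else s
}
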