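# GenBank flat-file and FASTA I/O.
#
# Only the slice of the GenBank grammar that annotated plastomes use is
# supported: single-entry files; gene/CDS/tRNA/rRNA features; locations built
# from ranges, join() and complement(); "<"/">" partial markers; /gene,
# /pseudo qualifiers. Everything else is carried past silently.

#' Read an annotated plastome from a GenBank flat file
#'
#' Parses a single-entry GenBank flat file into a [plastome_record()].
#' CDS/tRNA/rRNA features are captured with their join/complement locations
#' mapped to parts and strand; `gene` features marked `/pseudo` propagate the
#' pseudogene flag (and stand in for a missing CDS/tRNA/rRNA child).
#'
#' @param path Path to a GenBank flat file with one entry.
#' @return A [plastome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file: no LOCUS line",
                                call. = FALSE)
  toks <- strsplit(trimws(locus[1]), "[[:space:]]+")[[1]]
  id <- toks[2]
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("GenBank parse error: missing ORIGIN/sequence",
                              call. = FALSE)
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(end - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank parse error: empty sequence",
                              call. = FALSE)

  feats <- parse_genbank_features(lines, ori[1])
  build_record_from_genbank(id, sequence, circular, feats)
}

# scan the FEATURES block into a list of raw features
parse_genbank_features <- function(lines, origin_line) {
  fstart <- grep("^FEATURES", lines)
  raw <- list()
  if (length(fstart) == 0L) return(raw)
  i <- fstart[1] + 1L
  cur <- NULL
  while (i < origin_line) {
    ln <- lines[i]
    if (grepl("^ {5}\\S", ln)) {                      # new feature key
      if (!is.null(cur)) raw[[length(raw) + 1L]] <- cur
      key <- sub("^ +(\\S+).*$", "\\1", ln)
      loc <- trimws(substring(ln, 22))
      cur <- list(key = key, loc = loc, quals = character(0))
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
      } else if (nzchar(txt) && length(cur$quals) == 0L) {
        cur$loc <- paste0(cur$loc, txt)               # location continuation
      } else if (nzchar(txt) && length(cur$quals) > 0L) {
        cur$quals[length(cur$quals)] <-
          paste0(cur$quals[length(cur$quals)], txt)   # qualifier continuation
      }
    }
    i <- i + 1L
  }
  if (!is.null(cur)) raw[[length(raw) + 1L]] <- cur
  raw
}

qualifier_value <- function(quals, name) {
  pat <- paste0("^/", name, "=")
  hit <- grep(pat, quals, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  gsub('^"|"$', "", sub(pat, "", hit[1]))
}

has_flag <- function(quals, name) any(grepl(paste0("^/", name, "\\b"), quals))

# location grammar: range | complement(loc) | join(loc, ...) | order(loc, ...)
parse_location <- function(loc) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  if (startsWith(loc, "complement(")) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  elems <- strsplit(loc, ",", fixed = TRUE)[[1]]
  partial <- FALSE
  inner_comp <- grepl("^complement\\(", elems)
  if (any(inner_comp)) {
    if (!all(inner_comp))
      stop("unsupported mixed-strand location: ", loc, call. = FALSE)
    strand <- "-"
    elems <- sub("^complement\\((.*)\\)$", "\\1", elems)
  }
  parts <- t(vapply(elems, function(e) {
    if (grepl("[<>]", e)) partial <<- TRUE
    e <- gsub("[<>]", "", e)
    if (grepl("\\.\\.", e)) {
      as.integer(strsplit(e, "..", fixed = TRUE)[[1]][1:2])
    } else {
      rep(as.integer(e), 2L)
    }
  }, integer(2)))
  dimnames(parts) <- list(NULL, c("start", "end"))
  list(parts = parts, strand = strand, partial = partial)
}

build_record_from_genbank <- function(id, sequence, circular, raw) {
  keep <- c("CDS", "tRNA", "rRNA")
  rows <- list()
  pseudo_genes <- character(0)
  gene_feats <- list()
  for (f in raw) {
    if (f$key == "gene") {
      nm <- qualifier_value(f$quals, "gene")
      if (is.na(nm)) nm <- qualifier_value(f$quals, "locus_tag")
      if (has_flag(f$quals, "pseudo") || has_flag(f$quals, "pseudogene"))
        pseudo_genes <- c(pseudo_genes, nm)
      gene_feats[[length(gene_feats) + 1L]] <- c(f, list(name = nm))
    }
    if (!f$key %in% keep) next
    nm <- qualifier_value(f$quals, "gene")
    if (is.na(nm)) nm <- qualifier_value(f$quals, "locus_tag")
    if (is.na(nm)) nm <- qualifier_value(f$quals, "product")
    lp <- parse_location(f$loc)
    rows[[length(rows) + 1L]] <- gene_feature(
      name = nm, kind = f$key, parts = lp$parts, strand = lp$strand,
      pseudo = has_flag(f$quals, "pseudo") || has_flag(f$quals, "pseudogene"),
      partial = lp$partial
    )
  }
  feats <- if (length(rows)) do.call(rbind, rows) else feature_table()
  # gene-only pseudogenes (no typed child feature of the same name)
  for (g in gene_feats) {
    nm <- g$name
    if (is.na(nm) || nm %in% feats$name) next
    if (!(has_flag(g$quals, "pseudo") || has_flag(g$quals, "pseudogene"))) next
    lp <- parse_location(g$loc)
    kind <- if (grepl("^trn", nm)) "tRNA" else if (grepl("^rrn", nm)) "rRNA"
            else "CDS"
    feats <- rbind(feats, gene_feature(nm, kind, parts = lp$parts,
                                       strand = lp$strand, pseudo = TRUE))
  }
  if (length(pseudo_genes))
    feats$pseudo[feats$name %in% pseudo_genes] <- TRUE
  # genome order
  if (nrow(feats) > 0) {
    starts <- vapply(feats$parts, function(p) min(p[, 1]), numeric(1))
    feats <- feats[order(starts), , drop = FALSE]
    rownames(feats) <- NULL
  }
  plastome_record(id, sequence, circular, feats)
}

format_location <- function(parts, strand, partial = FALSE) {
  rngs <- apply(parts, 1L, function(r) {
    if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "..", r[2])
  })
  if (partial) rngs[1] <- paste0("<", rngs[1])
  s <- if (length(rngs) > 1L) paste0("join(", paste(rngs, collapse = ","), ")")
       else rngs
  if (strand == "-") paste0("complement(", s, ")") else s
}

#' Write a plastome record as a GenBank flat file
#'
#' Emits a minimal flat file (LOCUS, FEATURES, ORIGIN) that [read_genbank()]
#' round-trips losslessly for sequence and feature set.
#'
#' @param record A [plastome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2000",
                   record$id, record$length,
                   if (record$circular) "circular" else "linear"),
           sprintf("DEFINITION  %s plastome record.", record$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", record$length))
  f <- record$features
  for (i in seq_len(nrow(f))) {
    loc <- format_location(f$parts[[i]], f$strand[i], f$partial[i])
    out <- c(out,
             sprintf("     %-16s%s", f$kind[i], loc),
             sprintf('                     /gene="%s"', f$name[i]))
    if (f$pseudo[i]) out <- c(out, "                     /pseudo")
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
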