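# Shared sequence and genetic-code utilities. All coordinates in the package
# are 1-based inclusive (GenBank / IRanges convention).

# cache for lazily built lookup tables (NG86 pathway table etc.)
.plastomics_cache <- new.env(parent = emptyenv())

#' Plastid genetic code (NCBI translation table 11)
#'
#' Named character vector mapping DNA codons (e.g. \code{"ATG"}) to one-letter
#' amino acids, with \code{"*"} for stop codons. Table 11 is the
#' bacterial/plastid code used for all CDS validation and codon statistics.
#'
#' @return Named character vector of length 64.
#' @export
genetic_code_11 <- function() {
  gc <- .plastomics_cache$gc11
  if (is.null(gc)) {
    gc <- Biostrings::getGeneticCode("11")
    names(gc) <- chartr("U", "T", names(gc))
    .plastomics_cache$gc11 <- gc
  }
  gc
}

# all 64 codons in a fixed order (TTT, TTC, ...)
all_codons <- function() names(genetic_code_11())

sense_codons <- function() {
  gc <- genetic_code_11()
  names(gc)[gc != "*"]
}

stop_codons <- function() {
  gc <- genetic_code_11()
  names(gc)[gc == "*"]
}

# synonymous family sizes keyed by amino acid (sense codons only)
aa_family_sizes <- function() {
  gc <- genetic_code_11()
  table(gc[gc != "*"])
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings over \code{A,C,G,T,N}.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# complement without reversal
complement_seq <- function(x) chartr("ACGTN", "TGCAN", x)

# plain string reversal
reverse_seq <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Translate a coding sequence under translation table 11
#'
#' @param seq DNA string, length divisible by 3.
#' @return Single amino-acid string (\code{*} marks stops, \code{X} codons
#'   containing N).
#' @export
translate_cds <- function(seq) {
  stopifnot(nchar(seq) %% 3 == 0)
  cods <- split_codons(seq)
  gc <- genetic_code_11()
  aa <- gc[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# split a CDS into its codon vector
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  stopifnot(n %% 3 == 0)
  starts <- seq(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

# GC fraction of a string; N excluded from numerator and denominator
gc_fraction <- function(seq) {
  if (!nzchar(seq)) return(NA_real_)
  tab <- table(strsplit(seq, "")[[1]])
  acgt <- sum(tab[c("A", "C", "G", "T")], na.rm = TRUE)
  if (acgt == 0) return(NA_real_)
  sum(tab[c("G", "C")], na.rm = TRUE) / acgt
}

# draw random DNA of length n at a given GC fraction
random_dna <- function(n, gc = 0.365) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# validate a DNA string: only A,C,G,T,N allowed (upper-cased first)
check_dna <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop(sprintf("%s contains disallowed characters: %s", what,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  }
  seq
}
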