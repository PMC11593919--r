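# Codon usage bias: codon counts, RSCU, positional GC, Wright's effective
# number of codons (with the mutation-only expectation curve), PR2
# coordinates, and the neutrality regression of GC12 on GC3.

# coerce extract_cds() output / named vector to a plain character vector
as_cds_set <- function(cds_set) {
  if (is.data.frame(cds_set)) {
    stats::setNames(cds_set$seq,
                    if ("gene" %in% names(cds_set)) cds_set$gene else NULL)
  } else {
    out <- as.character(cds_set)
    names(out) <- names(cds_set)
    out
  }
}

#' Codon counts over a set of coding sequences
#'
#' @param cds_set Character vector of CDSs (each length divisible by 3), or
#'   the data frame returned by [extract_cds()].
#' @param include_stop Treat the three stop codons as a synonymous family in
#'   downstream RSCU (default `FALSE`: stops are tallied but carry no RSCU).
#' @return Object of class `codon_usage_table`: data frame with one row per
#'   codon (`codon` DNA form, `codon_rna`, `aa`, `count`), attributes
#'   `skipped` (codons containing N), `n_codons` and `include_stop`.
#' @export
codon_counts <- function(cds_set, include_stop = FALSE) {
  seqs <- as_cds_set(cds_set)
  if (length(seqs) == 0L) stop("empty CDS set", call. = FALSE)
  cods <- unlist(lapply(seqs, split_codons), use.names = FALSE)
  has_n <- grepl("N", cods, fixed = TRUE)
  skipped <- sum(has_n)
  cods <- cods[!has_n]
  gc11 <- genetic_code_11()
  tab <- table(factor(cods, levels = names(gc11)))
  out <- data.frame(codon = names(gc11),
                    codon_rna = chartr("T", "U", names(gc11)),
                    aa = unname(gc11), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "n_codons") <- length(cods)
  attr(out, "include_stop") <- include_stop
  class(out) <- c("codon_usage_table", class(out))
  out
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c = count(c) / (family total / family size): 1 means the
#' codon is used exactly as often as expected if its synonymous family were
#' used uniformly. Families with zero total get RSCU 0 and `absent = TRUE`.
#'
#' @param table A `codon_usage_table` from [codon_counts()].
#' @return The table with `family_size`, `rscu` and `absent` columns added.
#'   Stop codons have `NA` RSCU unless the table was built with
#'   `include_stop = TRUE`.
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  include_stop <- isTRUE(attr(table, "include_stop"))
  fam <- table$aa
  if (!include_stop) fam[table$aa == "*"] <- NA
  table$family_size <- as.integer(stats::ave(
    rep(1L, nrow(table)), fam, FUN = length))
  table$family_size[is.na(fam)] <- NA_integer_
  fam_total <- stats::ave(table$count, fam, FUN = sum)
  table$rscu <- ifelse(is.na(fam) | fam_total == 0, NA_real_,
                       table$count / (fam_total / table$family_size))
  table$absent <- !is.na(fam) & fam_total == 0
  table$rscu[table$absent] <- 0
  table
}

#' Positional GC content of coding sequences
#'
#' GC fraction at each codon position over the whole CDS, with the terminal
#' stop codon and any codon containing N excluded. GC12 is the arithmetic
#' mean of GC1 and GC2.
#'
#' @param cds Character vector of CDSs (optionally named by gene), or the
#'   data frame from [extract_cds()].
#' @return Data frame with columns `gene`, `n_codons`, `gc1`, `gc2`, `gc3`,
#'   `gc12`, `gc`; all fractions in `[0, 1]`, `NA` if no codon survives the
#'   exclusions.
#' @export
gc_by_position <- function(cds) {
  seqs <- as_cds_set(cds)
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("cds", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    cods <- coding_codons(seqs[[i]])
    if (length(cods) == 0L)
      return(data.frame(gene = nm[i], n_codons = 0L, gc1 = NA_real_,
                        gc2 = NA_real_, gc3 = NA_real_, gc12 = NA_real_,
                        gc = NA_real_, stringsAsFactors = FALSE))
    m <- do.call(rbind, strsplit(cods, ""))
    gcpos <- colMeans(matrix(m %in% c("G", "C"), ncol = 3L))
    data.frame(gene = nm[i], n_codons = length(cods),
               gc1 = gcpos[1], gc2 = gcpos[2], gc3 = gcpos[3],
               gc12 = (gcpos[1] + gcpos[2]) / 2, gc = mean(gcpos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# codons of a CDS usable for codon statistics: terminal stop and N-containing
# codons removed; internal stops removed as well (defensive)
coding_codons <- function(seq) {
  cods <- split_codons(seq)
  if (length(cods) && cods[length(cods)] %in% stop_codons())
    cods <- cods[-length(cods)]
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  cods[!cods %in% stop_codons()]
}

#' Effective number of codons (Wright's estimator)
#'
#' Per synonymous family with n codons observed and usage proportions p_i,
#' the codon homozygosity is F = (n * sum(p_i^2) - 1) / (n - 1). Families
#' with n <= 1 or F = 0 are excluded from their degeneracy-class average;
#' a missing threefold class (Ile) is imputed as (F2 + F4) / 2. ENC =
#' 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, clipped to [20, 61]. 20 means one codon
#' per amino acid (maximal bias); 61 means uniform synonymous usage.
#'
#' @param cds A single CDS string.
#' @return List with `enc`, class homozygosities `f2`, `f3`, `f4`, `f6`, and
#'   `defined`.
#' @export
enc <- function(cds) {
  cods <- coding_codons(cds)
  gc11 <- genetic_code_11()
  aa <- gc11[cods]
  sizes <- aa_family_sizes()
  fbar <- c(`2` = NA_real_, `3` = NA_real_, `4` = NA_real_, `6` = NA_real_)
  fs <- split(cods, aa)
  by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (a in names(fs)) {
    k <- sizes[[a]]
    if (is.null(k) || k == 1L) next
    n <- length(fs[[a]])
    if (n <= 1L) next
    p <- as.numeric(table(fs[[a]])) / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f == 0) next
    by_class[[as.character(k)]] <- c(by_class[[as.character(k)]], f)
  }
  for (cl in names(fbar))
    if (length(by_class[[cl]])) fbar[cl] <- mean(by_class[[cl]])
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"]))
    fbar["3"] <- (fbar[["2"]] + fbar[["4"]]) / 2
  if (anyNA(fbar))
    return(list(enc = NA_real_, f2 = fbar[["2"]], f3 = fbar[["3"]],
                f4 = fbar[["4"]], f6 = fbar[["6"]], defined = FALSE))
  val <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
    3 / fbar[["6"]]
  list(enc = min(max(val, 20), 61), f2 = fbar[["2"]], f3 = fbar[["3"]],
       f4 = fbar[["4"]], f6 = fbar[["6"]], defined = TRUE)
}

#' Expected ENC under mutation pressure alone
#'
#' Wright's null curve: ENC expected from GC3 alone when codon usage is
#' shaped only by the genome-wide GC3 composition,
#' 2 + s + 29 / (s^2 + (1 - s)^2) with s = GC3.
#'
#' @param gc3 Numeric vector of GC3 fractions in `[0, 1]`.
#' @return Expected ENC values (limit values at 0 and 1).
#' @export
enc_expected <- function(gc3) {
  stopifnot(all(gc3 >= 0 & gc3 <= 1, na.rm = TRUE))
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

# fourfold-degenerate codon boxes (first two bases) under table 11
fourfold_boxes <- function(mode = c("extended", "strict")) {
  mode <- match.arg(mode)
  strict <- c("GC", "GG", "CC", "AC", "GT")      # Ala Gly Pro Thr Val
  if (mode == "strict") strict else c(strict, "CT", "TC", "CG")  # +Leu Ser Arg
}

#' PR2 (parity rule 2) coordinates of a coding sequence
#'
#' Third-position base balance restricted to fourfold-degenerate codon
#' families: x = G3/(G3+C3) and y = A3/(A3+T3). At (0.5, 0.5) substitution
#' pressure on the third position is strand-symmetric.
#'
#' @param cds A single CDS string.
#' @param fourfold `"extended"` (default): the five strictly fourfold amino
#'   acids plus the fourfold boxes of Leu (CTN), Ser (TCN), Arg (CGN);
#'   `"strict"`: the five only.
#' @return List with `x`, `y`, third-position counts `a3,t3,g3,c3`, and
#'   `x_defined` / `y_defined` flags (denominator > 0).
#' @export
pr2 <- function(cds, fourfold = c("extended", "strict")) {
  boxes <- fourfold_boxes(match.arg(fourfold))
  cods <- coding_codons(cds)
  cods <- cods[substr(cods, 1L, 2L) %in% boxes]
  third <- substr(cods, 3L, 3L)
  cnt <- c(a3 = sum(third == "A"), t3 = sum(third == "T"),
           g3 = sum(third == "G"), c3 = sum(third == "C"))
  xd <- (cnt[["g3"]] + cnt[["c3"]]) > 0
  yd <- (cnt[["a3"]] + cnt[["t3"]]) > 0
  list(x = if (xd) cnt[["g3"]] / (cnt[["g3"]] + cnt[["c3"]]) else NA_real_,
       y = if (yd) cnt[["a3"]] / (cnt[["a3"]] + cnt[["t3"]]) else NA_real_,
       counts = cnt, x_defined = xd, y_defined = yd)
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 on GC3. A slope near 1 indicates
#' codon composition dominated by mutation pressure (positions drift
#' together); a slope near 0 indicates selection decoupling the first two
#' positions from the third.
#'
#' @param profiles Data frame with columns `gc12` and `gc3`
#'   (from [gc_by_position()]).
#' @return Object of class `neutrality_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`, and the underlying `lm` fit.
#' @export
neutrality_regression <- function(profiles) {
  d <- profiles[stats::complete.cases(profiles[, c("gc12", "gc3")]), ]
  if (nrow(d) < 3L) stop("need at least 3 genes with defined GC12 and GC3",
                         call. = FALSE)
  if (stats::sd(d$gc3) == 0) stop("GC3 is constant: slope undefined",
                                  call. = FALSE)
  fit <- stats::lm(gc12 ~ gc3, data = d)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared, n = nrow(d), fit = fit),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "neutrality regression (GC12 ~ GC3, %d genes):\n  slope %.4f, intercept %.4f, R-squared %.4f\n",
    x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Per-gene codon-usage profile
#'
#' Convenience wrapper computing, for every CDS in a set, positional GC, ENC
#' and PR2 coordinates in one table.
#'
#' @param cds_set Character vector of CDSs or the frame from [extract_cds()].
#' @param fourfold PR2 fourfold-family mode, see [pr2()].
#' @return Data frame: `gene`, `n_codons`, `gc1..gc3`, `gc12`, `gc`, `enc`,
#'   `pr2_x`, `pr2_y`.
#' @export
codon_usage_profile <- function(cds_set, fourfold = "extended") {
  seqs <- as_cds_set(cds_set)
  prof <- gc_by_position(seqs)
  prof$enc <- vapply(seqs, function(s) enc(s)$enc, numeric(1),
                     USE.NAMES = FALSE)
  pr <- lapply(seqs, pr2, fourfold = fourfold)
  prof$pr2_x <- vapply(pr, `[[`, numeric(1), "x")
  prof$pr2_y <- vapply(pr, `[[`, numeric(1), "y")
  prof
}
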