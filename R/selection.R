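# Pairwise Ka/Ks estimation. Core estimator: Nei & Gojobori (1986) site and
# difference counting with Jukes-Cantor correction. An approximate
# transition/transversion-weighted variant ("YN-approx") is available behind
# the same interface and labelled per result.

# per-codon synonymous site counts (stop-codon targets count as
# nonsynonymous, so synonymous + nonsynonymous sites sum to 3 per codon)
ng86_syn_sites <- function() {
  tab <- .plastomics_cache$ng86_sites
  if (!is.null(tab)) return(tab)
  gc11 <- genetic_code_11()
  bases <- c("A", "C", "G", "T")
  tab <- vapply(names(gc11), function(cod) {
    if (gc11[[cod]] == "*") return(NA_real_)
    s <- 0
    for (p in 1:3) for (b in bases) {
      if (b == substr(cod, p, p)) next
      alt <- cod
      substr(alt, p, p) <- b
      if (gc11[[alt]] == gc11[[cod]]) s <- s + 1 / 3
    }
    s
  }, numeric(1))
  .plastomics_cache$ng86_sites <- tab
  tab
}

# syn/nonsyn differences between two codons, averaged over minimal mutation
# pathways; pathways through stop codons are discarded (all-blocked pairs
# fall back to using every pathway)
ng86_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  memo <- .plastomics_cache$ng86_paths
  if (is.null(memo)) {
    memo <- new.env(parent = emptyenv())
    .plastomics_cache$ng86_paths <- memo
  }
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  gc11 <- genetic_code_11()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- if (length(pos) == 1L) list(pos) else {
    pm <- permutations_of(length(pos))
    lapply(seq_len(nrow(pm)), function(r) pos[pm[r, ]])
  }
  score_path <- function(order) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc11[[nxt]] == "*") blocked <- TRUE
      if (gc11[[nxt]] == gc11[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  sc <- t(vapply(perms, score_path, numeric(3)))
  use <- sc[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(sc))
  out <- c(sd = mean(sc[use, "sd"]), nd = mean(sc[use, "nd"]))
  memo[[key]] <- out
  out
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Protein-guided codon alignment of two coding sequences
#'
#' Aligns the translations globally (BLOSUM62) and back-maps the amino-acid
#' columns to codons; columns with a gap on either side, or a codon
#' containing N, are removed so the result is a gap-free codon-wise pairing.
#'
#' @param cds1,cds2 CDS strings (length divisible by 3, terminal stop
#'   allowed and stripped).
#' @param gene Optional gene label carried into results.
#' @param identity_floor Amino-acid identity below which a
#'   "non-orthologous pair" warning is raised (default 0.3).
#' @param drop_stop_columns If `TRUE`, columns where either codon is a stop
#'   are removed instead of raising an error (useful for simulated data
#'   where mutation may create a stop). Default `FALSE`: an internal stop is
#'   an error.
#' @return Object of class `codon_alignment`: `gene`, codon vectors
#'   `codons1`, `codons2`, `n_codons`, `identity`, `removed_columns`.
#' @export
align_codons <- function(cds1, cds2, gene = NA_character_,
                         identity_floor = 0.3, drop_stop_columns = FALSE) {
  strip <- function(s) {
    stopifnot(nchar(s) %% 3 == 0)
    cods <- split_codons(toupper(s))
    if (length(cods) && cods[length(cods)] %in% stop_codons())
      cods <- cods[-length(cods)]
    cods
  }
  k1 <- strip(cds1); k2 <- strip(cds2)
  gc11 <- genetic_code_11()
  aa_of <- function(cods) {
    a <- gc11[cods]; a[is.na(a)] <- "X"
    if (any(a == "*") && !drop_stop_columns)
      stop("internal stop codon in CDS", call. = FALSE)
    paste(a, collapse = "")
  }
  a1 <- aa_of(k1); a2 <- aa_of(k2)
  if (identical(a1, a2) && length(k1) == length(k2)) {
    p1 <- seq_along(k1); p2 <- seq_along(k2)
  } else {
    if (is.null(.plastomics_cache$blosum62)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      .plastomics_cache$blosum62 <- e$BLOSUM62
    }
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a1), Biostrings::AAString(a2), type = "global",
      substitutionMatrix = .plastomics_cache$blosum62,
      gapOpening = 10, gapExtension = 0.5)
    s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    i1 <- cumsum(s1 != "-"); i2 <- cumsum(s2 != "-")
    keep <- s1 != "-" & s2 != "-"
    p1 <- i1[keep]; p2 <- i2[keep]
  }
  c1 <- k1[p1]; c2 <- k2[p2]
  ok <- !grepl("N", c1, fixed = TRUE) & !grepl("N", c2, fixed = TRUE)
  if (drop_stop_columns)
    ok <- ok & !(c1 %in% stop_codons()) & !(c2 %in% stop_codons())
  removed <- (max(length(k1), length(k2)) - sum(ok))
  c1 <- c1[ok]; c2 <- c2[ok]
  ident <- if (length(c1)) mean(gc11[c1] == gc11[c2]) else NA_real_
  if (!is.na(ident) && ident < identity_floor)
    warning(sprintf("non-orthologous pair%s: amino-acid identity %.2f",
                    if (is.na(gene)) "" else paste0(" (", gene, ")"), ident),
            call. = FALSE)
  structure(list(gene = gene, codons1 = c1, codons2 = c2,
                 n_codons = length(c1), identity = ident,
                 removed_columns = removed),
            class = "codon_alignment")
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)   # saturated
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Synonymous/nonsynonymous site counts come from enumerating the three
#' single-base mutations at every codon position under translation table 11
#' (mutations to stops count as nonsynonymous, so the two site classes sum
#' to 3 per codon); observed differences are resolved over equally weighted
#' minimal mutation pathways with stop-codon pathways discarded. The
#' proportions are Jukes-Cantor corrected, d = -(3/4) ln(1 - (4/3) p).
#'
#' @param alignment A `codon_alignment` from [align_codons()].
#' @param exclusion_threshold Results with ratio >= this (or an undefined
#'   ratio) are flagged excluded (default 45).
#' @return Object of class `kaks_result`: `gene`, `ka`, `ks`, `ratio`,
#'   site/difference counts, `method`, `excluded`, `reason`.
#' @export
kaks_ng86 <- function(alignment, exclusion_threshold = 45) {
  stopifnot(inherits(alignment, "codon_alignment"),
            alignment$n_codons >= 1L)
  sites <- ng86_syn_sites()
  S <- (sum(sites[alignment$codons1]) + sum(sites[alignment$codons2])) / 2
  N <- 3 * alignment$n_codons - S
  dd <- mapply(function(a, b) ng86_diffs(a, b),
               alignment$codons1, alignment$codons2)
  Sd <- sum(dd["sd", ]); Nd <- sum(dd["nd", ])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- jc_correct(ps); ka <- jc_correct(pn)
  finish_kaks(alignment$gene, ka, ks, S, N, Sd, Nd, "NG86",
              exclusion_threshold)
}

finish_kaks <- function(gene, ka, ks, S, N, Sd, Nd, method, thr) {
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  excluded <- is.na(ratio) || ratio >= thr
  reason <- if (!excluded) NA_character_
            else if (is.na(ka) || is.na(ks)) "rate undefined (saturation)"
            else if (ks == 0) "Ks = 0 (ratio NA)"
            else sprintf("ratio >= %g", thr)
  structure(list(gene = gene, ka = ka, ks = ks, ratio = ratio,
                 syn_sites = S, nonsyn_sites = N, syn_diffs = Sd,
                 nonsyn_diffs = Nd, method = method, excluded = excluded,
                 reason = reason),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka/Ks (%s)%s: Ka = %s, Ks = %s, ratio = %s%s\n", x$method,
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              format(x$ka, digits = 4), format(x$ks, digits = 4),
              format(x$ratio, digits = 4),
              if (x$excluded) paste0("  (excluded: ", x$reason, ")") else ""))
  invisible(x)
}

#' Ka/Ks by a transition/transversion-weighted approximation
#'
#' Approximate variant: mutational-opportunity site counting weights each
#' possible change by kappa (transitions) or 1 (transversions), with kappa
#' estimated from the observed transition/transversion difference ratio of
#' the pair; differences and distance correction as in [kaks_ng86()].
#' Labelled `"YN-approx"` in results so figures can state the method
#' honestly.
#'
#' @inheritParams kaks_ng86
#' @return A `kaks_result` with `method = "YN-approx"`.
#' @export
kaks_yn_approx <- function(alignment, exclusion_threshold = 45) {
  stopifnot(inherits(alignment, "codon_alignment"),
            alignment$n_codons >= 1L)
  # observed transition/transversion split over differing aligned bases
  b1 <- unlist(strsplit(alignment$codons1, ""))
  b2 <- unlist(strsplit(alignment$codons2, ""))
  diff <- b1 != b2
  is_ts <- function(x, y) paste0(pmin(x, y), pmax(x, y)) %in% c("AG", "CT")
  ts <- sum(diff & is_ts(b1, b2)); tv <- sum(diff & !is_ts(b1, b2))
  kappa <- if (tv == 0) 10 else max(0.1, 2 * ts / tv)
  gc11 <- genetic_code_11()
  bases <- c("A", "C", "G", "T")
  syn_w <- function(cod) {
    s <- 0; tot <- 0
    for (p in 1:3) {
      ref <- substr(cod, p, p)
      wsum <- 0; wsyn <- 0
      for (b in bases) {
        if (b == ref) next
        w <- if (is_ts(ref, b)) kappa else 1
        wsum <- wsum + w
        alt <- cod; substr(alt, p, p) <- b
        if (gc11[[alt]] == gc11[[cod]]) wsyn <- wsyn + w
      }
      s <- s + wsyn / wsum
    }
    s
  }
  u <- unique(c(alignment$codons1, alignment$codons2))
  sw <- vapply(u, syn_w, numeric(1))
  S <- (sum(sw[alignment$codons1]) + sum(sw[alignment$codons2])) / 2
  N <- 3 * alignment$n_codons - S
  dd <- mapply(function(a, b) ng86_diffs(a, b),
               alignment$codons1, alignment$codons2)
  Sd <- sum(dd["sd", ]); Nd <- sum(dd["nd", ])
  ks <- jc_correct(if (S > 0) Sd / S else NA_real_)
  ka <- jc_correct(if (N > 0) Nd / N else NA_real_)
  finish_kaks(alignment$gene, ka, ks, S, N, Sd, Nd, "YN-approx",
              exclusion_threshold)
}

#' Pairwise Ka/Ks over shared genes of several records
#'
#' For every unordered pair of records and every shared functional CDS gene
#' (IR duplicates collapsed): align codons, estimate Ka/Ks, and apply the
#' exclusion rule (ratio undefined or >= `exclusion_threshold`).
#'
#' @param records List of >= 2 [plastome_record()] objects.
#' @param gene_list Genes to analyse; default all genes shared by each pair.
#'   Genes absent from a record give a row with `reason = "absent"`.
#' @param method `"NG86"` (default) or `"YN-approx"`.
#' @param exclusion_threshold See [kaks_ng86()].
#' @return Long data frame: `gene`, `species1`, `species2`, `method`, `ka`,
#'   `ks`, `ratio`, `excluded`, `reason`.
#' @export
pairwise_kaks_matrix <- function(records, gene_list = NULL, method = "NG86",
                                 exclusion_threshold = 45) {
  stopifnot(length(records) >= 2L)
  method <- match.arg(method, c("NG86", "YN-approx"))
  est <- if (method == "NG86") kaks_ng86 else kaks_yn_approx
  cds <- lapply(records, extract_cds, dedupe_ir_copies = TRUE)
  ids <- vapply(records, `[[`, "", "id")
  rows <- list()
  for (i in seq_along(records)[-length(records)])
    for (j in (i + 1L):length(records)) {
      genes <- if (is.null(gene_list))
        intersect(cds[[i]]$gene, cds[[j]]$gene) else gene_list
      for (g in genes) {
        s1 <- cds[[i]]$seq[match(g, cds[[i]]$gene)]
        s2 <- cds[[j]]$seq[match(g, cds[[j]]$gene)]
        if (is.na(s1) || is.na(s2)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, species1 = ids[i], species2 = ids[j], method = method,
            ka = NA_real_, ks = NA_real_, ratio = NA_real_, excluded = TRUE,
            reason = "absent", stringsAsFactors = FALSE)
          next
        }
        r <- est(align_codons(s1, s2, gene = g),
                 exclusion_threshold = exclusion_threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, species1 = ids[i], species2 = ids[j], method = method,
          ka = r$ka, ks = r$ks, ratio = r$ratio, excluded = r$excluded,
          reason = ifelse(is.na(r$reason), NA_character_, r$reason),
          stringsAsFactors = FALSE)
      }
    }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
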