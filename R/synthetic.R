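# Synthetic plastomes with machine-readable planted truth: quadripartite
# structure, gene models, codon-usage distribution, SSRs, dispersed repeats,
# and controlled ortholog divergence.

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Uniform-within-family codon distribution
#'
#' @return Named numeric vector over the 61 sense codons: conditional
#'   probability of each codon given its amino acid (uniform, so every RSCU
#'   equals 1 in expectation).
#' @export
uniform_codon_distribution <- function() {
  gc11 <- genetic_code_11()
  sense <- names(gc11)[gc11 != "*"]
  sizes <- aa_family_sizes()
  stats::setNames(1 / as.numeric(sizes[gc11[sense]]), sense)
}

check_codon_distribution <- function(p) {
  gc11 <- genetic_code_11()
  sense <- names(gc11)[gc11 != "*"]
  stopifnot(all(sense %in% names(p)), all(p >= 0))
  fam_sum <- tapply(p[sense], gc11[sense], sum)
  if (any(abs(fam_sum - 1) > 1e-6))
    stop("codon_distribution: probabilities within each synonymous family ",
         "must sum to 1", call. = FALSE)
  p[sense]
}

#' Default synthetic gene models
#'
#' A representative plastome gene complement scaled to the requested region
#' lengths: photosynthesis and self-replication CDSs plus tRNAs in the LSC,
#' rRNA operon genes in the IR (duplicated by construction), a small-SSC
#' gene, and one pseudogenized NDH gene.
#'
#' @param lsc,ir,ssc Region lengths the models must fit into.
#' @return Data frame: `name`, `kind`, `region`, `length`, `strand`,
#'   `pseudo`.
#' @export
default_gene_models <- function(lsc, ir, ssc) {
  g <- data.frame(
    name  = c("psbA", "matK", "rbcL", "atpA", "rpoB", "trnH-GUG", "trnK-UUU",
              "ndhB", "rrn16", "rrn23", "trnV-GAC", "ccsA"),
    kind  = c("CDS", "CDS", "CDS", "CDS", "CDS", "tRNA", "tRNA",
              "CDS", "rRNA", "rRNA", "tRNA", "CDS"),
    region = c("LSC", "LSC", "LSC", "LSC", "LSC", "LSC", "LSC",
               "LSC", "IR", "IR", "IR", "SSC"),
    length = c(1062, 1530, 1428, 1524, 3213, 74, 72, 1533, 1491, 2810, 72,
               960),
    strand = c("+", "-", "+", "+", "-", "+", "+", "+", "+", "+", "+", "+"),
    pseudo = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
               FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  fits <- function(region, cap) {
    sub <- g[g$region == region, ]
    keep <- cumsum(sub$length + 80) < cap * 0.9
    sub$name[keep]
  }
  keep <- c(fits("LSC", lsc), fits("IR", ir), fits("SSC", ssc))
  g[g$name %in% keep, , drop = FALSE]
}

#' Specification for a synthetic plastome
#'
#' Defaults mirror a real orchid plastome: region lengths LSC 83,689 bp,
#' IR 35,027 bp, SSC 4,915 bp and background GC 0.365. Planted elements are
#' positioned randomly (non-overlapping) within their regions and recorded
#' in the truth table.
#'
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param lsc,ir,ssc Region lengths in bp.
#' @param genes Gene models (see [default_gene_models()]).
#' @param codon_distribution Conditional per-codon probabilities within each
#'   synonymous family (names = DNA codons); default uniform within family.
#' @param planted_ssrs Data frame `motif`, `count`, `region` or `NULL`.
#' @param planted_repeats Data frame `kind` (`F/R/P/C`), `length`,
#'   `separation` (bp between arms), `region`, or `NULL`.
#' @param base_gc Background GC fraction.
#' @return Object of class `synthetic_plastome_spec`.
#' @export
synthetic_plastome_spec <- function(seed = 1L, lsc = 83689, ir = 35027,
                                    ssc = 4915,
                                    genes = default_gene_models(lsc, ir, ssc),
                                    codon_distribution = NULL,
                                    planted_ssrs = NULL,
                                    planted_repeats = NULL,
                                    base_gc = 0.365) {
  stopifnot(lsc > 0, ir > 0, ssc > 0, base_gc > 0, base_gc < 1)
  if (is.null(codon_distribution))
    codon_distribution <- uniform_codon_distribution()
  codon_distribution <- check_codon_distribution(codon_distribution)
  for (pl in list(planted_ssrs, planted_repeats)) {
    if (!is.null(pl) && !all(pl$region %in% c("LSC", "SSC")))
      stop("planted SSRs/repeats must lie in LSC or SSC (IR content is ",
           "duplicated by construction)", call. = FALSE)
  }
  if (!is.null(genes) && nrow(genes) > 0) {
    stopifnot(all(genes$kind %in% c("CDS", "tRNA", "rRNA")),
              all(genes$region %in% c("LSC", "IR", "SSC")),
              all(genes$strand %in% c("+", "-")))
    bad <- genes$kind == "CDS" & genes$length %% 3 != 0
    if (any(bad)) stop("CDS gene length must be divisible by 3: ",
                       paste(genes$name[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(seed = as.integer(seed), lsc = lsc, ir = ir, ssc = ssc,
                 genes = genes, codon_distribution = codon_distribution,
                 planted_ssrs = planted_ssrs,
                 planted_repeats = planted_repeats, base_gc = base_gc),
            class = "synthetic_plastome_spec")
}

# sample n codons from the conditional distribution (amino acid uniform over
# the 20 sense amino acids, codon from its family conditional)
sample_codons <- function(n, p) {
  gc11 <- genetic_code_11()
  sense <- names(p)
  aa <- gc11[sense]
  pick_aa <- sample(unique(aa), n, replace = TRUE)
  vapply(pick_aa, function(a) {
    fam <- sense[aa == a]
    if (length(fam) == 1L) fam else sample(fam, 1L, prob = p[fam])
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic plastome with planted truth
#'
#' Builds a circular quadripartite genome: background sequence at the
#' requested GC, genes instantiated with start/stop codons and codons drawn
#' from the spec's codon distribution, IRa the exact reverse complement of
#' IRb (IR gene copies annotated on both arms), and planted SSRs / dispersed
#' repeats at recorded coordinates. After assembly the background is screened
#' for accidental SSRs or long repeats meeting the default detection
#' thresholds and re-rolled (up to `max_retries`) so the genome contains
#' exactly the planted elements.
#'
#' @param spec A [synthetic_plastome_spec()].
#' @param id Record id (default `"synth1"`).
#' @param screen Screen for background collisions (default `TRUE`).
#' @param max_retries Background re-rolls before giving up (default 20).
#' @return List of class `synthetic_plastome` with elements `record`
#'   (a [plastome_record()]) and `truth` (partition, gene, SSR and repeat
#'   truth tables plus the seed).
#' @export
generate_plastome <- function(spec, id = "synth1", screen = TRUE,
                              max_retries = 20L) {
  stopifnot(inherits(spec, "synthetic_plastome_spec"))
  with_seed(spec$seed, {
    for (attempt in seq_len(max_retries)) {
      out <- try(assemble_plastome(spec, id, screen), silent = TRUE)
      if (!inherits(out, "try-error")) return(out)
    }
    stop("could not generate a collision-free plastome in ", max_retries,
         " attempts: ", attr(out, "condition")$message, call. = FALSE)
  })
}

assemble_plastome <- function(spec, id, screen) {
  regions <- list(LSC = spec$lsc, IR = spec$ir, SSC = spec$ssc)
  placed <- list(LSC = list(), IR = list(), SSC = list())
  seqs <- lapply(regions, function(n) random_dna(n, spec$base_gc))

  reserve <- function(region, len) {
    cap <- regions[[region]]
    # free gaps between already-placed intervals, with a 1 bp margin
    iv <- placed[[region]]
    occ <- if (length(iv)) do.call(rbind, iv) else
      matrix(integer(0), ncol = 2)
    occ <- occ[order(occ[, 1]), , drop = FALSE]
    gaps <- list(); lo <- 2L
    for (r in seq_len(nrow(occ))) {
      if (occ[r, 1] - 2L >= lo) gaps[[length(gaps) + 1L]] <- c(lo, occ[r, 1] - 2L)
      lo <- max(lo, occ[r, 2] + 2L)
    }
    if (cap - 1L >= lo) gaps[[length(gaps) + 1L]] <- c(lo, cap - 1L)
    fit <- Filter(function(g) g[2] - g[1] + 1L >= len, gaps)
    if (length(fit) == 0L)
      stop("could not place a ", len, " bp element in ", region,
           " without overlap", call. = FALSE)
    slots <- vapply(fit, function(g) g[2] - g[1] + 2L - len, numeric(1))
    g <- fit[[sample.int(length(fit), 1L, prob = slots)]]
    s <- g[1] + sample.int(g[2] - g[1] + 2L - len, 1L) - 1L
    e <- s + len - 1L
    placed[[region]][[length(placed[[region]]) + 1L]] <<- c(s, e)
    c(s, e)
  }
  insert <- function(region, at, piece) {
    s <- seqs[[region]]
    seqs[[region]] <<- paste0(substr(s, 1L, at[1] - 1L), piece,
                              substr(s, at[2] + 1L, nchar(s)))
  }

  # reserve all placements first, largest element first, so big genes are
  # never squeezed out by fragmentation
  genes <- spec$genes
  ps <- spec$planted_ssrs
  pr <- spec$planted_repeats
  req <- rbind(
    if (NROW(genes)) data.frame(type = "gene", idx = seq_len(nrow(genes)),
                                region = genes$region,
                                span = genes$length),
    if (NROW(ps)) data.frame(type = "ssr", idx = seq_len(nrow(ps)),
                             region = ps$region,
                             span = nchar(ps$motif) * ps$count + 2L),
    if (NROW(pr)) data.frame(type = "rep", idx = seq_len(nrow(pr)),
                             region = pr$region,
                             span = 2L * pr$length + pr$separation))
  slots <- list(gene = list(), ssr = list(), rep = list())
  if (!is.null(req)) {
    for (r in order(-req$span))
      slots[[req$type[r]]][[req$idx[r]]] <- reserve(req$region[r],
                                                    req$span[r])
  }

  gene_rows <- list()
  for (i in seq_len(NROW(genes))) {
    glen <- genes$length[i]
    body <- if (genes$kind[i] == "CDS") {
      ncod <- glen / 3 - 2L
      cods <- sample_codons(ncod, spec$codon_distribution)
      if (genes$pseudo[i] && ncod > 2L)
        cods[ceiling(ncod / 2)] <- "TAA"          # internal stop: pseudogene
      paste0("ATG", paste(cods, collapse = ""), "TAA")
    } else random_dna(glen, spec$base_gc)
    at <- slots$gene[[i]]
    insert(genes$region[i],
           at, if (genes$strand[i] == "-") revcomp(body) else body)
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      name = genes$name[i], kind = genes$kind[i], region = genes$region[i],
      start = at[1], end = at[2], strand = genes$strand[i],
      pseudo = genes$pseudo[i], stringsAsFactors = FALSE)
  }

  ssr_rows <- list()
  for (i in seq_len(NROW(ps))) {
    motif <- toupper(ps$motif[i]); cnt <- ps$count[i]
    u <- nchar(motif)
    run <- strrep(motif, cnt)
    at <- slots$ssr[[i]]                           # breakers on both flanks
    brk <- function(b) if (b == "C") "G" else "C"  # never extends an ACGT run
    piece <- paste0(brk(substr(motif, u, u)), run, brk(substr(motif, 1, 1)))
    insert(ps$region[i], at, piece)
    ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
      motif = motif, unit_length = u, repeat_count = cnt,
      region = ps$region[i], start = at[1] + 1L,
      end = at[1] + nchar(run), stringsAsFactors = FALSE)
  }

  rep_rows <- list()
  for (i in seq_len(NROW(pr))) {
    L <- pr$length[i]; sep <- pr$separation[i]; kind <- pr$kind[i]
    arm <- random_dna(L, spec$base_gc)
    arm2 <- switch(kind, F = arm, R = reverse_seq(arm), P = revcomp(arm),
                   C = complement_seq(arm))
    at <- slots$rep[[i]]
    piece <- paste0(arm, random_dna(sep, spec$base_gc), arm2)
    insert(pr$region[i], at, piece)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      kind = kind, length = L, start1 = at[1], end1 = at[1] + L - 1L,
      start2 = at[1] + L + sep, end2 = at[1] + 2L * L + sep - 1L,
      region = pr$region[i], stringsAsFactors = FALSE)
  }

  # junction breakers: the first base of LSC (resp. SSC) must not complement
  # its last base, otherwise maximal IR extension overshoots the planted arm
  for (rg in c("LSC", "SSC")) {
    s <- seqs[[rg]]
    bad <- complement_seq(substr(s, nchar(s), nchar(s)))
    if (substr(s, 1L, 1L) == bad) {
      substr(s, 1L, 1L) <- setdiff(c("A", "C", "G", "T"), bad)[1]
      seqs[[rg]] <- s
    }
  }
  # assemble LSC | IRb | SSC | IRa with IRa = revcomp(IRb)
  irb <- seqs$IR
  genome <- paste0(seqs$LSC, irb, seqs$SSC, revcomp(irb))
  off <- c(LSC = 0L, IR = spec$lsc, SSC = spec$lsc + spec$ir)
  n <- nchar(genome)
  ira_start <- spec$lsc + spec$ir + spec$ssc
  irb_end_abs <- spec$lsc + spec$ir

  to_abs <- function(df, cols) {
    for (cl in cols) df[[cl]] <- df[[cl]] + off[df$region]
    df
  }
  gene_truth <- if (length(gene_rows)) to_abs(do.call(rbind, gene_rows),
                                              c("start", "end")) else NULL
  ssr_truth <- if (length(ssr_rows)) to_abs(do.call(rbind, ssr_rows),
                                            c("start", "end")) else NULL
  rep_truth <- if (length(rep_rows))
    to_abs(do.call(rbind, rep_rows),
           c("start1", "end1", "start2", "end2")) else NULL

  # mirror IR features onto the IRa arm
  feats <- list()
  add_feat <- function(nm, kind, s, e, strand, pseudo)
    feats[[length(feats) + 1L]] <<- gene_feature(nm, kind, s, e,
                                                 strand = strand,
                                                 pseudo = pseudo)
  if (!is.null(gene_truth)) {
    extra <- list()
    for (i in seq_len(nrow(gene_truth))) {
      g <- gene_truth[i, ]
      add_feat(g$name, g$kind, g$start, g$end, g$strand, g$pseudo)
      if (g$region == "IR") {
        s2 <- ira_start + (irb_end_abs - g$end) + 1L
        e2 <- ira_start + (irb_end_abs - g$start) + 1L
        flip <- if (g$strand == "+") "-" else "+"
        add_feat(g$name, g$kind, s2, e2, flip, g$pseudo)
        extra[[length(extra) + 1L]] <- data.frame(
          name = g$name, kind = g$kind, region = "IRa", start = s2, end = e2,
          strand = flip, pseudo = g$pseudo, stringsAsFactors = FALSE)
      }
    }
    if (length(extra)) gene_truth <- rbind(gene_truth,
                                           do.call(rbind, extra))
    gene_truth$region[gene_truth$region == "IR"] <- "IRb"
  }
  record <- plastome_record(id, genome, circular = TRUE,
                            features = if (length(feats))
                              do.call(rbind, feats) else NULL)
  truth <- list(
    seed = spec$seed,
    partition = list(lsc = spec$lsc, ir = spec$ir, ssc = spec$ssc,
                     starts = c(LSC = 1L, IRb = spec$lsc + 1L,
                                SSC = spec$lsc + spec$ir + 1L,
                                IRa = ira_start + 1L)),
    genes = gene_truth, ssrs = ssr_truth, repeats = rep_truth)

  if (screen) screen_collisions(record, truth)
  structure(list(record = record, truth = truth),
            class = "synthetic_plastome")
}

# fail (-> caller re-rolls the background) if detection finds anything that
# was not planted
screen_collisions <- function(record, truth) {
  found <- find_ssrs(record$sequence)
  planted <- truth$ssrs
  key <- function(d) paste(d$motif, d$start, d$repeat_count)
  extra <- if (is.null(planted)) found else
    found[!key(found) %in% key(planted), , drop = FALSE]
  if (nrow(extra) > 0)
    stop("accidental SSR in background at ", extra$start[1], call. = FALSE)
  if (!is.null(planted) && nrow(extra) == 0 &&
      nrow(found) != nrow(planted))
    stop("planted SSR not recovered verbatim", call. = FALSE)
  # near-threshold exact repeats (>= 25 bp) other than the planted ones and
  # the IR pair itself
  part <- partition_from_lengths(truth$partition$lsc, truth$partition$ir,
                                 truth$partition$ssc)
  reps <- find_dispersed_repeats(record$sequence, min_length = 25,
                                 max_mismatch = 0, mask_partition = part)
  if (!is.null(truth$repeats) && nrow(reps) > 0) {
    # a detected pair is accounted for when both arms overlap planted arms
    # (maximal extension may legitimately overshoot a planted arm slightly)
    arms <- rbind(as.matrix(truth$repeats[, c("start1", "end1")]),
                  as.matrix(truth$repeats[, c("start2", "end2")]))
    touches <- function(s, e) any(s <= arms[, 2] & e >= arms[, 1])
    planted_hit <- vapply(seq_len(nrow(reps)), function(i)
      touches(reps$start1[i], reps$end1[i]) &&
      touches(reps$start2[i], reps$end2[i]), logical(1))
    reps <- reps[!planted_hit, , drop = FALSE]
  }
  if (nrow(reps) > 0)
    stop("accidental dispersed repeat in background at ", reps$start1[1],
         call. = FALSE)
  invisible(TRUE)
}

#' Write a synthetic truth table as JSON
#'
#' @param truth The `truth` element of a `synthetic_plastome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Diverge the orthologous content of a plastome
#'
#' Produces a mutated copy of the record: every functional CDS has its
#' synonymous positions substituted at `syn_rate` and nonsynonymous
#' positions at `nonsyn_rate` (classes re-derived on the current codon by
#' single-base enumeration under table 11; substitutions that would create a
#' stop codon are never proposed), and intergenic positions are substituted
#' at `igs_rate`. Applied changes are counted into the truth table.
#'
#' @param record A [plastome_record()].
#' @param syn_rate,nonsyn_rate,igs_rate Per-position substitution
#'   probabilities in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param igs_loci Optional character vector of IGS locus names (as produced
#'   by [extract_loci()]) to restrict intergenic mutation to.
#' @param new_id Id of the mutated record (default `"<id>_div"`).
#' @return List of class `synthetic_plastome`: mutated `record` and `truth`
#'   with per-gene `syn_applied` / `nonsyn_applied` and per-IGS change
#'   counts.
#' @export
mutate_orthologs <- function(record, syn_rate, nonsyn_rate, igs_rate,
                             seed = 1L, igs_loci = NULL,
                             new_id = paste0(record$id, "_div")) {
  stopifnot(syn_rate >= 0, syn_rate < 0.5, nonsyn_rate >= 0,
            nonsyn_rate < 0.5, igs_rate >= 0, igs_rate < 0.5)
  with_seed(seed, mutate_orthologs_impl(record, syn_rate, nonsyn_rate,
                                        igs_rate, igs_loci, new_id))
}

mutate_orthologs_impl <- function(record, syn_rate, nonsyn_rate, igs_rate,
                                  igs_loci, new_id) {
  seq_chars <- strsplit(record$sequence, "")[[1]]
  gc11 <- genetic_code_11()
  bases <- c("A", "C", "G", "T")
  f <- record$features
  gene_truth <- list()
  for (i in seq_len(nrow(f))) {
    if (f$kind[i] != "CDS" || f$pseudo[i]) next
    s <- splice_feature(record, i)
    if (nchar(s) %% 3 != 0) next
    cods <- split_codons(s)
    syn_applied <- 0L; nonsyn_applied <- 0L
    for (ci in seq_along(cods)) {
      cod <- cods[ci]
      if (gc11[cod] %in% c("*", NA) || grepl("N", cod, fixed = TRUE)) next
      for (p in 1:3) {
        ref <- substr(cod, p, p)
        syn_alt <- character(0); non_alt <- character(0)
        for (b in bases) {
          if (b == ref) next
          alt <- cod; substr(alt, p, p) <- b
          if (gc11[alt] == "*") next
          if (gc11[alt] == gc11[cod]) syn_alt <- c(syn_alt, b)
          else non_alt <- c(non_alt, b)
        }
        u <- stats::runif(1)
        if (u < syn_rate && length(syn_alt)) {
          substr(cod, p, p) <- if (length(syn_alt) == 1L) syn_alt else
            sample(syn_alt, 1L)
          syn_applied <- syn_applied + 1L
        } else if (u >= syn_rate && u < syn_rate + nonsyn_rate &&
                   length(non_alt)) {
          substr(cod, p, p) <- if (length(non_alt) == 1L) non_alt else
            sample(non_alt, 1L)
          nonsyn_applied <- nonsyn_applied + 1L
        }
      }
      cods[ci] <- cod
    }
    mutated <- paste(cods, collapse = "")
    if (f$strand[i] == "-") mutated <- revcomp(mutated)
    # write back through the parts in genomic join order
    pos <- 1L
    parts <- f$parts[[i]]
    for (r in seq_len(nrow(parts))) {
      plen <- parts[r, 2] - parts[r, 1] + 1L
      idx <- seq.int(parts[r, 1], parts[r, 2])
      idx <- ((idx - 1L) %% record$length) + 1L
      seq_chars[idx] <- strsplit(substr(mutated, pos, pos + plen - 1L),
                                 "")[[1]]
      pos <- pos + plen
    }
    gene_truth[[length(gene_truth) + 1L]] <- data.frame(
      gene = f$name[i], copy_index = f$copy_index[i],
      syn_applied = syn_applied, nonsyn_applied = nonsyn_applied,
      stringsAsFactors = FALSE)
  }
  # intergenic mutation
  igs_truth <- NULL
  loci <- extract_loci(record)
  igs <- loci[loci$kind == "IGS", , drop = FALSE]
  if (!is.null(igs_loci)) igs <- igs[igs$name %in% igs_loci, , drop = FALSE]
  if (igs_rate > 0 && nrow(igs) > 0) {
    counts <- integer(nrow(igs))
    for (r in seq_len(nrow(igs))) {
      idx <- seq.int(igs$start[r], igs$end[r])
      idx <- ((idx - 1L) %% record$length) + 1L
      hit <- idx[stats::runif(length(idx)) < igs_rate]
      for (h in hit)
        seq_chars[h] <- sample(setdiff(bases, seq_chars[h]), 1L)
      counts[r] <- length(hit)
    }
    igs_truth <- data.frame(locus = igs$name, length = igs$end - igs$start + 1L,
                            changes = counts,
                            expected_divergence = igs_rate,
                            stringsAsFactors = FALSE)
  }
  rec2 <- plastome_record(new_id, paste(seq_chars, collapse = ""),
                          record$circular, record$features)
  truth <- list(genes = if (length(gene_truth)) do.call(rbind, gene_truth)
                else NULL,
                igs = igs_truth,
                rates = list(syn = syn_rate, nonsyn = nonsyn_rate,
                             igs = igs_rate))
  structure(list(record = rec2, truth = truth),
            class = "synthetic_plastome")
}
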