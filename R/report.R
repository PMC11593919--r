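# Headline report: one pass over a record producing the summary numbers a
# comparative plastome paper tabulates, plus TSV/JSON writers.

#' Full analysis summary of one plastome record
#'
#' Runs structure detection, gene inventory, codon-usage statistics, SSR and
#' dispersed-repeat detection on a record and collects the headline numbers
#' (partition lengths, regional GC, gene counts, top codons, ENC range,
#' neutrality fit, SSR tallies by unit length/region/context, repeat tallies
#' by kind).
#'
#' @param record A [plastome_record()].
#' @param min_ir_length Passed to [detect_inverted_repeats()].
#' @param partition Optional precomputed `quadripartite_partition`.
#' @param dedupe_ir_copies CDS set convention for codon statistics (default
#'   `TRUE`: IR duplicates collapsed); recorded in the output metadata.
#' @return List of class `plastome_summary`.
#' @export
plastome_report <- function(record, min_ir_length = 1000, partition = NULL,
                            dedupe_ir_copies = TRUE) {
  if (is.null(partition))
    partition <- detect_inverted_repeats(record$sequence, record$circular,
                                         min_ir_length = min_ir_length)
  gc <- regional_gc(record, partition)
  inv <- count_genes(record)
  cds <- extract_cds(record, dedupe_ir_copies = dedupe_ir_copies)
  cu <- rscu(codon_counts(cds))
  prof <- codon_usage_profile(cds)
  neut <- if (nrow(prof) >= 3 && stats::sd(prof$gc3, na.rm = TRUE) > 0)
    neutrality_regression(prof) else NULL
  ssrs <- find_ssrs(record$sequence)
  if (nrow(ssrs) > 0) ssrs <- classify_ssr_location(ssrs, record, partition)
  reps <- find_dispersed_repeats(record$sequence, mask_partition = partition)
  sense <- cu[cu$aa != "*", ]
  structure(list(
    id = record$id,
    genome_length = record$length,
    partition = partition,
    regional_gc = gc,
    genes = inv,
    cds_mode = if (dedupe_ir_copies) "ir-deduplicated" else "all-copies",
    n_cds = nrow(cds),
    codon_table = cu,
    top_codons = sense[order(-sense$count), ][1:3, c("codon_rna", "count")],
    n_high_rscu = sum(sense$rscu > 1, na.rm = TRUE),
    high_rscu_au_ending = sum(sense$rscu > 1 &
                                substr(sense$codon, 3, 3) %in% c("A", "T"),
                              na.rm = TRUE),
    gene_profile = prof,
    enc_range = range(prof$enc, na.rm = TRUE),
    enc_mean = mean(prof$enc, na.rm = TRUE),
    neutrality = neut,
    ssrs = ssrs,
    ssr_by_unit = if (nrow(ssrs)) table(ssrs$unit_length) else table(integer()),
    ssr_by_region = if (nrow(ssrs)) table(ssrs$region) else table(character()),
    ssr_by_context = if (nrow(ssrs)) table(ssrs$context) else
      table(character()),
    repeats = reps,
    repeat_by_kind = if (nrow(reps)) table(reps$kind) else table(character())
  ), class = "plastome_summary")
}

#' @export
print.plastome_summary <- function(x, ...) {
  cat(sprintf("plastome summary for '%s' (%s bp)\n", x$id,
              format(x$genome_length, big.mark = ",")))
  l <- x$partition$lengths
  cat(sprintf("  partition: LSC %s | IR %s | SSC %s bp\n",
              format(l[["LSC"]], big.mark = ","),
              format(x$partition$ir_length, big.mark = ","),
              format(l[["SSC"]], big.mark = ",")))
  cat(sprintf("  GC: overall %.2f%%, LSC %.2f%%, IR %.2f%%, SSC %.2f%%\n",
              100 * x$regional_gc[["overall"]], 100 * x$regional_gc[["LSC"]],
              100 * x$regional_gc[["IRb"]], 100 * x$regional_gc[["SSC"]]))
  cat(sprintf("  genes: %d unique, %d duplicated, %d total (CDS %d / tRNA %d / rRNA %d)\n",
              x$genes$unique_genes, x$genes$duplicated_genes,
              x$genes$total_genes, x$genes$by_kind[["CDS"]],
              x$genes$by_kind[["tRNA"]], x$genes$by_kind[["rRNA"]]))
  cat(sprintf("  codon usage (%s, %d CDS): ENC %.2f-%.2f (mean %.2f), %d codons with RSCU > 1\n",
              x$cds_mode, x$n_cds, x$enc_range[1], x$enc_range[2],
              x$enc_mean, x$n_high_rscu))
  if (!is.null(x$neutrality))
    cat(sprintf("  neutrality: slope %.4f, R-squared %.4f\n",
                x$neutrality$slope, x$neutrality$r_squared))
  cat(sprintf("  SSRs: %d (%s)\n", nrow(x$ssrs),
              paste(sprintf("%s-mer: %s", names(x$ssr_by_unit),
                            x$ssr_by_unit), collapse = ", ")))
  cat(sprintf("  dispersed repeats: %d (%s)\n", nrow(x$repeats),
              paste(sprintf("%s: %s", names(x$repeat_by_kind),
                            x$repeat_by_kind), collapse = ", ")))
  invisible(x)
}

#' Serialize a plastome summary to JSON
#'
#' @param summary A `plastome_summary` from [plastome_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(summary, path) {
  x <- summary
  out <- list(
    id = x$id, genome_length = x$genome_length,
    partition = as.list(x$partition$lengths),
    ir_length = x$partition$ir_length,
    regional_gc_percent = as.list(round(100 * x$regional_gc, 2)),
    genes = x$genes[c("unique_genes", "duplicated_genes", "total_genes")],
    genes_by_kind = as.list(x$genes$by_kind),
    cds_mode = x$cds_mode,
    n_high_rscu = x$n_high_rscu,
    high_rscu_au_ending = x$high_rscu_au_ending,
    enc = list(min = x$enc_range[1], max = x$enc_range[2], mean = x$enc_mean),
    neutrality = if (is.null(x$neutrality)) NULL else
      list(slope = x$neutrality$slope, r_squared = x$neutrality$r_squared),
    ssr_total = nrow(x$ssrs),
    ssr_by_unit = as.list(x$ssr_by_unit),
    ssr_by_region = as.list(x$ssr_by_region),
    ssr_by_context = as.list(x$ssr_by_context),
    repeat_total = nrow(x$repeats),
    repeat_by_kind = as.list(x$repeat_by_kind)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a data frame as a TSV report
#'
#' @param df Data frame (list columns are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
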