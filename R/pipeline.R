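#' Run the full species-discrimination pipeline
#'
#' Chains the analysis stages over a set of barcode loci and (optionally)
#' a genotype matrix. For every single locus and every requested locus
#' combination it computes a genetic-diversity table row (aligned
#' length, variable characters, nucleotide diversity, Tajima's D, mean
#' intraspecific and interspecific K2P distance and their ratio),
#' best-match and best-close-match identification rates, and an NJ tree
#' with its monophyly-based discrimination rate. For genotype input it
#' applies the site filter, screens the species-diagnostic SNP key and
#' computes pairwise Fst for all species pairs.
#'
#' Every value in the returned tables is unrounded; rounding is applied
#' only when tables are written (distances to 4 decimals, the
#' intra/inter ratio to 3 significant figures, allele frequencies to 5
#' decimals).
#'
#' @param alignments named list of [locus_alignment()] objects.
#' @param combinations named list of character vectors of locus names
#'   to concatenate; by default every single locus plus the all-locus
#'   combination.
#' @param genotype optional [genotype_matrix()].
#' @param threshold_percentile percentile of intraspecific distances
#'   used as the best-close-match threshold.
#' @param bootstrap_replicates NJ bootstrap replicates (0 = skip).
#' @param estimator Fst estimator, see [pairwise_fst()].
#' @param filter_thresholds named numeric vector with elements
#'   `max_major_af`, `max_missing`, `max_het` for [filter_sites()].
#' @param seed integer seed used for bootstrap resampling.
#' @param out_dir optional output directory for TSV/Newick reports;
#'   created if absent.
#' @param overwrite allow overwriting existing files in `out_dir`.
#' @return list of class `pipeline_report` with elements
#'   `barcode_table`, `match_table`, `trees`, `monophyly`,
#'   `summaries`, `genotype` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(alignments, combinations = NULL, genotype = NULL,
                         threshold_percentile = 95,
                         bootstrap_replicates = 0L,
                         estimator = "nei_gst",
                         filter_thresholds = c(max_major_af = 0.95,
                                               max_missing = 0.05,
                                               max_het = 0.20),
                         seed = 1L, out_dir = NULL, overwrite = FALSE) {
  if (length(alignments) == 0L) stopf("no alignments supplied (stage: input)")
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, `[[`, "", "locus_name")
  if (is.null(combinations)) {
    combinations <- as.list(stats::setNames(names(alignments), names(alignments)))
    if (length(alignments) > 1L)
      combinations[[paste(names(alignments), collapse = " + ")]] <-
        names(alignments)
  }
  bad <- setdiff(unique(unlist(combinations)), names(alignments))
  if (length(bad) > 0L)
    stopf("combination references undeclared loci: %s (stage: config)",
          paste(bad, collapse = ", "))

  barcode_rows <- list(); match_rows <- list()
  trees <- list(); monophyly <- list(); summaries <- list()
  for (nm in names(combinations)) {
    loci <- combinations[[nm]]
    aln <- if (length(loci) == 1L) alignments[[loci]] else
      concatenate_loci(alignments[loci], name = nm)
    div <- tajimas_d(aln)
    dm <- distance_matrix(aln)
    ds <- distance_summary(dm)
    thr <- intraspecific_threshold(ds, threshold_percentile)
    bm <- best_match(dm)
    reports <- list(best_match = bm)
    if (!is.na(thr)) reports$best_close_match <- best_close_match(dm, threshold = thr)
    tree <- if (length(aln$accessions) >= 3L &&
                !anyNA(dm$d[upper.tri(dm$d)])) nj_tree(dm) else NULL
    if (!is.null(tree) && bootstrap_replicates > 0L)
      tree <- bootstrap_support(aln, bootstrap_replicates, seed = seed)$tree
    mono <- if (!is.null(tree)) monophyly_rate(tree, aln$species) else NULL
    barcode_rows[[nm]] <- data.frame(
      barcode = nm, aligned_length = div$L,
      variable_characters = div$S, pi = div$pi, tajima_D = div$tajima_D,
      mean_intra = ds$mean_intra, mean_inter = ds$mean_inter,
      ratio = ds$ratio,
      nj_monophyly_rate = if (is.null(mono)) NA_real_ else mono$rate)
    mr <- bba_summary(reports)
    mr <- cbind(barcode = nm, test = mr$marker, mr[, -1, drop = FALSE])
    match_rows[[nm]] <- mr
    trees[[nm]] <- tree
    monophyly[[nm]] <- mono
    summaries[[nm]] <- ds
  }
  barcode_table <- do.call(rbind, barcode_rows)
  match_table <- do.call(rbind, match_rows)
  rownames(barcode_table) <- rownames(match_table) <- NULL

  geno <- NULL
  if (!is.null(genotype)) {
    filtered <- filter_sites(genotype,
                             filter_thresholds[["max_major_af"]],
                             filter_thresholds[["max_missing"]],
                             filter_thresholds[["max_het"]])
    key <- screen_diagnostic(filtered)
    geno <- list(filter_summary = attr(filtered, "filter_summary"),
                 site_stats = site_stats(filtered),
                 key = key,
                 fst = fst_matrix(filtered, estimator))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("barcodekey")),
    seed = seed,
    threshold_percentile = threshold_percentile,
    bootstrap_replicates = bootstrap_replicates,
    fst_estimator = estimator,
    filter_thresholds = as.list(filter_thresholds),
    distance_model = "K2P, pairwise deletion",
    loci = names(alignments),
    combinations = combinations,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  report <- structure(list(barcode_table = barcode_table,
                           match_table = match_table, trees = trees,
                           monophyly = monophyly, summaries = summaries,
                           genotype = geno, manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir, overwrite)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d barcode rows, genotype stage %s\n",
              nrow(x$barcode_table),
              if (is.null(x$genotype)) "absent" else "present"))
  tab <- x$barcode_table
  tab$pi <- round(tab$pi, 4); tab$tajima_D <- round(tab$tajima_D, 3)
  tab$mean_intra <- round(tab$mean_intra, 4)
  tab$mean_inter <- round(tab$mean_inter, 4)
  tab$ratio <- signif(tab$ratio, 3)
  tab$nj_monophyly_rate <- round(tab$nj_monophyly_rate, 2)
  print(tab)
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits the barcode table, match-rate table, per-combination Newick
#' trees and distance summaries, and (when present) the genotype-stage
#' outputs (filter summary, site statistics, diagnostic key, Fst
#' table), all as TSV / Newick text. Rounded presentation values are
#' pure formattings of the unrounded values in the report object.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory.
#' @param overwrite allow overwriting existing files.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir, overwrite = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  emit <- function(fname) {
    path <- file.path(out_dir, fname)
    if (file.exists(path) && !overwrite)
      stopf("refusing to overwrite '%s' (use overwrite = TRUE)", path)
    path
  }
  tab <- report$barcode_table
  tab$pi <- round(tab$pi, 4); tab$tajima_D <- round(tab$tajima_D, 3)
  tab$mean_intra <- round(tab$mean_intra, 4)
  tab$mean_inter <- round(tab$mean_inter, 4)
  tab$ratio <- signif(tab$ratio, 3)
  utils::write.table(tab, emit("barcode_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$match_table, emit("match_rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(report$trees)) {
    if (is.null(report$trees[[nm]])) next
    safe <- gsub("[^A-Za-z0-9._-]+", "_", nm)
    ape::write.tree(report$trees[[nm]], emit(paste0("nj_", safe, ".nwk")))
  }
  if (!is.null(report$genotype)) {
    g <- report$genotype
    utils::write.table(g$filter_summary, emit("filter_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    st <- g$site_stats
    st$major_allele_freq <- formatC(round_half_up(st$major_allele_freq, 5),
                                    format = "f", digits = 5)
    utils::write.table(st, emit("site_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_diagnostic_key(g$key, emit("diagnostic_key.tsv"))
    utils::write.table(g$fst, emit("fst_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- report$manifest
  lines <- vapply(names(manifest), function(k)
    paste0(k, " = ", paste(unlist(manifest[[k]]), collapse = ", ")), "")
  writeLines(lines, emit("manifest.txt"))
  invisible(out_dir)
}
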