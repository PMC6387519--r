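# Cohort orchestration: detection -> attributes -> ranking/signatures ->
# length analyses -> annotation, with all report tables written to disk.

#' Run the full SSR analysis over a cohort manifest
#'
#' For every organism in the manifest (in `order`): scans the FASTA, writes
#' a BED of records, computes genome summary and per-class statistics, then
#' across the cohort builds the master table, the enrichment score matrix
#' (JSON export), clade signature tests (when `clades` is given), unit-length
#' histograms with length-preference peaks and subgroup prevalence, and —
#' for organisms with a GFF — exon/intron/intergenic annotation with
#' region composition. Reruns with the same inputs produce byte-identical
#' outputs.
#'
#' @param manifest Tibble (or TSV path) with columns `organism_id`, `fasta`,
#'   optional `gff`, `group`, `subgroup`, `order`.
#' @param out_dir Output directory, created if needed.
#' @param min_length,max_k Detection settings (defaults 12 and 6).
#' @param clades Optional named list of organism-id vectors for signature
#'   tests.
#' @param linkage Linkage method for class clustering (default `"average"`).
#' @param p_adjust_method Multiple-testing correction for signature tests
#'   (default `"bonferroni"`).
#' @return Invisibly, a list with all result tables (`summaries`,
#'   `master`, `class_stats`, `score_matrix`, `class_order`, `signatures`,
#'   `peaks`, `prevalence`, `annotation`, `composition`).
#' @export
run_cohort <- function(manifest, out_dir, min_length = 12, max_k = 6,
                       clades = NULL, linkage = "average",
                       p_adjust_method = "bonferroni") {
  if (is.character(manifest)) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE)
  }
  req <- c("organism_id", "fasta", "group", "subgroup", "order")
  if (!all(req %in% names(manifest))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$organism_id)) {
    stop("duplicate organism ids in manifest", call. = FALSE)
  }
  manifest <- dplyr::arrange(manifest, .data$order)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(org, what, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", what, "' failed for ", org, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  per_org <- purrr::map(seq_len(nrow(manifest)), function(i) {
    org <- manifest$organism_id[i]
    scan <- stage(org, "detect",
                  scan_fasta(manifest$fasta[i], min_length, max_k))
    write_ssr_bed(scan$records, file.path(out_dir, paste0(org, ".bed")))
    summ <- stage(org, "summarize",
                  summarize_genome(scan$records, scan$sequences, org))
    cls <- stage(org, "summarize",
                 per_class_stats(scan$records, summ$genome_size_bp, org,
                                 max_k))
    ann <- comp <- NULL
    if ("gff" %in% names(manifest) && !is.na(manifest$gff[i]) &&
        nzchar(manifest$gff[i])) {
      idx <- stage(org, "annotate", build_feature_index(manifest$gff[i]))
      ann <- stage(org, "annotate", annotate_records(scan$records, idx))
      write_annotated_bed(ann, file.path(out_dir,
                                         paste0(org, "_annotated.bed")))
      comp <- stage(org, "annotate", region_composition(ann, max_k)) |>
        dplyr::mutate(organism_id = org, .before = 1)
    }
    list(records = scan$records, summary = summ, class_stats = cls,
         annotation = ann, composition = comp,
         hist = unit_length_histogram(scan$records, organism_id = org))
  })
  summaries <- purrr::map_dfr(per_org, "summary")
  class_stats <- purrr::map_dfr(per_org, "class_stats")
  master <- master_table(summaries,
                         manifest[c("organism_id", "group", "subgroup")])
  readr::write_tsv(master, file.path(out_dir, "master_table.tsv"))
  readr::write_tsv(class_stats, file.path(out_dir, "class_stats.tsv"))
  write_class_table(enumerate_classes(max_k),
                    file.path(out_dir, "repeat_classes.tsv"))
  sm <- build_score_matrix(class_stats,
                           organism_order = manifest$organism_id)
  write_heatmap_json(sm, file.path(out_dir, "score_matrix.json"))
  ord <- if (length(sm$classes) >= 2) cluster_classes(sm, linkage) else NULL
  if (!is.null(ord)) {
    writeLines(ord$order, file.path(out_dir, "class_cluster_order.txt"))
  }
  sig <- NULL
  if (!is.null(clades)) {
    sig <- signature_scan(class_stats, clades,
                          p_adjust_method = p_adjust_method)
    readr::write_tsv(sig, file.path(out_dir, "signatures.tsv"))
  }
  hists <- purrr::map_dfr(per_org, "hist")
  peaks <- detect_length_preference(hists)
  readr::write_tsv(peaks, file.path(out_dir, "length_preference_peaks.tsv"))
  prev <- preference_prevalence(
    peaks, manifest[c("organism_id", "subgroup")])
  readr::write_tsv(prev, file.path(out_dir, "preference_prevalence.tsv"))
  annotation <- purrr::map_dfr(per_org, "annotation")
  composition <- purrr::map_dfr(per_org, "composition")
  if (nrow(composition)) {
    readr::write_tsv(composition, file.path(out_dir,
                                            "region_composition.tsv"))
  }
  log_lines <- c(
    paste0("ssrscape run ", utils::packageVersion("ssrscape")),
    paste0("min_length\t", min_length),
    paste0("max_k\t", max_k),
    paste0("linkage\t", linkage),
    paste0("p_adjust\t", p_adjust_method),
    "coordinates\tBED 0-based half-open",
    "genome_size\tincludes N bases",
    "genomic_gc\tnon-N bases only",
    "overlap_rule\tleft-to-right greedy, longest run, ties to smaller k",
    paste0("organisms\t", paste(manifest$organism_id, collapse = ","))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(summaries = summaries, master = master,
                 class_stats = class_stats, score_matrix = sm,
                 class_order = ord, signatures = sig, peaks = peaks,
                 prevalence = prev, annotation = annotation,
                 composition = composition))
}
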