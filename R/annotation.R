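# Genomic annotation of SSRs against GFF3 gene models: exon / intron /
# intergenic assignment, exon-overlap percentage and distance to the nearest
# transcription start site (TSS).
#
# Interval arithmetic is done with GenomicRanges/IRanges; user-facing inputs
# and outputs stay tabular. Exons are merged across isoforms before introns
# (gene span minus exons) are derived; intergenic space is everything outside
# merged gene spans. The TSS is the strand-aware 5' end of each gene.

#' Build a feature index from a GFF3 file
#'
#' Reads `gene` and `exon` features (NCBI-dialect rows such as `region` or
#' `pseudogene` are ignored), merges exon intervals across isoforms, derives
#' introns as gene bodies minus exons, and records TSS positions. Genes
#' without exon children are treated as single-exon genes (with a message);
#' exons extending outside every gene span are clipped with a warning.
#'
#' @param gff_path Path to a GFF3 file (1-based inclusive coordinates, as
#'   per the standard; converted internally to 0-based half-open).
#' @return An `ssr_feature_index`: list of `GRanges` (`genes`, `exons`,
#'   `introns`) and a `tss` tibble (`seq_id`, `pos` 0-based, `strand`,
#'   `gene_id`).
#' @export
build_feature_index <- function(gff_path) {
  gff <- tryCatch(
    rtracklayer::readGFF(gff_path,
                         columns = c("seqid", "source", "type", "start",
                                     "end", "strand"),
                         tags = c("ID", "Parent")),
    error = function(e) stop("malformed GFF3 (", gff_path, "): ",
                             conditionMessage(e), call. = FALSE)
  )
  if (any(is.na(gff$start) | is.na(gff$end) | gff$end < gff$start)) {
    bad <- which(is.na(gff$start) | is.na(gff$end) | gff$end < gff$start)[1]
    stop("malformed GFF3 coordinates at feature line ", bad, call. = FALSE)
  }
  genes_df <- gff[gff$type == "gene", , drop = FALSE]
  exons_df <- gff[gff$type == "exon", , drop = FALSE]
  if (nrow(genes_df) == 0) stop("no gene features in ", gff_path,
                                call. = FALSE)
  genes <- GenomicRanges::GRanges(
    genes_df$seqid, IRanges::IRanges(genes_df$start, genes_df$end),
    strand = genes_df$strand,
    gene_id = as.character(genes_df$ID)
  )
  if (nrow(exons_df) > 0) {
    exons <- GenomicRanges::GRanges(
      exons_df$seqid, IRanges::IRanges(exons_df$start, exons_df$end))
  } else {
    exons <- GenomicRanges::GRanges()
  }
  # genes with no exon inside them become single-exon genes
  bare <- if (length(exons)) {
    S4Vectors::queryHits(GenomicRanges::findOverlaps(genes, exons,
                                                     type = "any"))
  } else integer(0)
  no_exon <- setdiff(seq_along(genes), unique(bare))
  if (length(no_exon)) {
    message(length(no_exon),
            " gene(s) without exon children treated as single-exon")
    exons <- c(exons, GenomicRanges::granges(genes[no_exon]))
  }
  # clip exons that stick out of every gene span
  within_gene <- GenomicRanges::countOverlaps(
    exons, genes, type = "within", ignore.strand = TRUE) > 0
  if (any(!within_gene)) {
    warning(sum(!within_gene),
            " exon(s) extend outside gene spans; clipped", call. = FALSE)
    out <- exons[!within_gene]
    hit <- GenomicRanges::findOverlaps(out, genes, select = "first",
                                       ignore.strand = TRUE)
    out <- out[!is.na(hit)]
    clipped <- suppressWarnings(GenomicRanges::pintersect(
      out, GenomicRanges::granges(genes)[hit[!is.na(hit)]],
      ignore.strand = TRUE))
    exons <- c(exons[within_gene], GenomicRanges::granges(clipped))
  }
  exons <- GenomicRanges::reduce(exons, ignore.strand = TRUE)
  gene_spans <- GenomicRanges::reduce(GenomicRanges::granges(genes),
                                      ignore.strand = TRUE)
  introns <- GenomicRanges::setdiff(gene_spans, exons, ignore.strand = TRUE)
  plus <- as.character(GenomicRanges::strand(genes)) != "-"
  tss <- tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(genes)),
    pos = ifelse(plus, GenomicRanges::start(genes) - 1L,
                 GenomicRanges::end(genes) - 1L),  # 0-based position
    strand = ifelse(plus, "+", "-"),
    gene_id = genes$gene_id
  )
  structure(list(genes = genes, exons = exons, introns = introns, tss = tss),
            class = "ssr_feature_index")
}

records_to_granges <- function(records) {
  GenomicRanges::GRanges(records$seq_id,
                         IRanges::IRanges(records$start + 1L, records$end))
}

#' Annotate SSR records with genomic region and TSS distance
#'
#' Assigns each SSR to `exon`, `intron` or `intergenic` by any-overlap with
#' precedence exon > intron > intergenic (the exon-overlap percentage keeps
#' boundary-spanning calls auditable). TSS distance is the unsigned distance
#' from the nearest SSR boundary to the nearest TSS on the same sequence
#' (0 when the SSR overlaps a TSS).
#'
#' @param records SSR record tibble.
#' @param index `ssr_feature_index` from [build_feature_index()].
#' @param unknown_seq How to treat records on sequences absent from the
#'   index: `"intergenic"` (default, with a warning) or `"error"`.
#' @return `records` plus `region`, `exon_overlap_pct` (exonic records only,
#'   `NA` otherwise) and `tss_distance` (`NA` when the sequence has no TSS).
#' @export
annotate_records <- function(records, index,
                             unknown_seq = c("intergenic", "error")) {
  stopifnot(inherits(index, "ssr_feature_index"))
  unknown_seq <- match.arg(unknown_seq)
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, region = character(0),
                         exon_overlap_pct = numeric(0),
                         tss_distance = numeric(0)))
  }
  known <- unique(c(as.character(GenomicRanges::seqnames(index$genes)),
                    index$tss$seq_id))
  if (!all(records$seq_id %in% known)) {
    msg <- paste(setdiff(unique(records$seq_id), known), collapse = ", ")
    if (unknown_seq == "error") {
      stop("sequences absent from annotation: ", msg, call. = FALSE)
    }
    warning("sequences absent from annotation treated as intergenic: ", msg,
            call. = FALSE)
  }
  gr <- records_to_granges(records)
  exon_bp <- overlap_bp(gr, index$exons)
  intron_bp <- overlap_bp(gr, index$introns)
  region <- dplyr::case_when(
    exon_bp > 0 ~ "exon",
    intron_bp > 0 ~ "intron",
    .default = "intergenic"
  )
  exon_pct <- ifelse(region == "exon", 100 * exon_bp / records$length_bp,
                     NA_real_)
  tss_distance <- vapply(seq_len(nrow(records)), function(i) {
    pos <- index$tss$pos[index$tss$seq_id == records$seq_id[i]]
    if (length(pos) == 0) return(NA_real_)
    inside <- pos >= records$start[i] & pos < records$end[i]
    if (any(inside)) return(0)
    min(pmin(abs(pos - records$start[i]), abs(pos - (records$end[i] - 1L))))
  }, numeric(1))
  records |>
    dplyr::mutate(region = region, exon_overlap_pct = exon_pct,
                  tss_distance = tss_distance)
}

overlap_bp <- function(query, subject) {
  if (length(subject) == 0) return(numeric(length(query)))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE))
  if (length(hits) == 0) return(numeric(length(query)))
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(query)[S4Vectors::queryHits(hits)],
    IRanges::ranges(subject)[S4Vectors::subjectHits(hits)]))
  out <- numeric(length(query))
  agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Motif-size composition of SSR bases per region
#'
#' For each region (and overall), the percentage of SSR-covered bases
#' contributed by each motif size k = 1..max_k. Each region's percentages
#' sum to 100.
#'
#' @param annotated Tibble from [annotate_records()].
#' @param max_k Largest motif size (default 6).
#' @return Tibble `region` (`exon`, `intron`, `intergenic`, `overall`), `k`,
#'   `bases`, `pct`. Regions with zero SSR bases are omitted.
#' @export
region_composition <- function(annotated, max_k = 6) {
  stopifnot(nrow(annotated) >= 1)
  per_region <- annotated |>
    dplyr::bind_rows(dplyr::mutate(annotated, region = "overall")) |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(k = seq_len(max_k)) |>
        dplyr::left_join(
          dplyr::count(df, .data$k, wt = .data$length_bp, name = "bases"),
          by = "k") |>
        dplyr::mutate(bases = dplyr::coalesce(as.numeric(.data$bases), 0),
                      pct = 100 * .data$bases / sum(.data$bases))
    }) |>
    dplyr::ungroup()
  per_region[order(match(per_region$region,
                         c("exon", "intron", "intergenic", "overall"))), ]
}

#' Write annotated SSR records as extended BED TSV
#'
#' BED6+ columns of [write_ssr_bed()] plus `region`, `exon_overlap_pct`,
#' `tss_distance`.
#'
#' @param annotated Tibble from [annotate_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_bed <- function(annotated, path) {
  bed <- annotated |>
    dplyr::transmute(.data$seq_id, .data$start, .data$end, .data$repeat_class,
                     .data$length_bp, strand = "+", .data$actual_motif,
                     .data$units, .data$region, .data$exon_overlap_pct,
                     .data$tss_distance)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
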