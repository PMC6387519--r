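# Per-organism SSR attributes: frequency, base coverage, density, GC.

# GC bases in the first `len` characters of `motif` repeated in tandem.
# Exact because detected repeats are perfect copies of their actual motif.
gc_bases_in_repeat <- function(motif, len) {
  k <- nchar(motif)
  gc_unit <- stringr::str_count(motif, "[GC]")
  full <- len %/% k
  rest <- len %% k
  gc_rest <- ifelse(rest > 0,
                    stringr::str_count(substr(motif, 1, rest), "[GC]"), 0L)
  full * gc_unit + gc_rest
}

#' Summarise SSR content of one genome
#'
#' Computes the master-table attributes for one organism: total SSR count
#' (frequency), bases covered, density (bp covered per Mb of genome) and the
#' GC fraction of the concatenation of all repeat sequences. Genome size is
#' the total assembly length including `N` bases; genomic GC is computed over
#' non-`N` bases only.
#'
#' @param records SSR record tibble from [scan_fasta()].
#' @param sequence_stats Per-sequence tibble from [scan_fasta()]
#'   (`seq_id`, `length_bp`, `gc_fraction`, `n_count`).
#' @param organism_id Identifier for the organism.
#' @return One-row tibble: `organism_id`, `genome_size_bp`,
#'   `genomic_gc_fraction`, `ssr_frequency`, `ssr_bases`, `ssr_density`
#'   (bp/Mb) and `ssr_gc_fraction` (`NA` when the genome carries no SSR).
#' @export
summarize_genome <- function(records, sequence_stats, organism_id) {
  if (nrow(sequence_stats) == 0 || sum(sequence_stats$length_bp) == 0) {
    stop("empty genome for ", organism_id, call. = FALSE)
  }
  if (nrow(records) > 0 &&
      !all(records$seq_id %in% sequence_stats$seq_id)) {
    stop("records reference sequences missing from sequence_stats",
         call. = FALSE)
  }
  genome_size <- sum(sequence_stats$length_bp)
  non_n <- sequence_stats$length_bp - sequence_stats$n_count
  genomic_gc <- if (sum(non_n) > 0) {
    sum(sequence_stats$gc_fraction * non_n, na.rm = TRUE) / sum(non_n)
  } else NA_real_
  ssr_bases <- sum(records$length_bp)
  ssr_gc <- if (nrow(records) > 0) {
    sum(gc_bases_in_repeat(records$actual_motif, records$length_bp)) /
      ssr_bases
  } else NA_real_
  tibble::tibble(
    organism_id = organism_id,
    genome_size_bp = genome_size,
    genomic_gc_fraction = genomic_gc,
    ssr_frequency = nrow(records),
    ssr_bases = ssr_bases,
    ssr_density = ssr_bases / genome_size * 1e6,
    ssr_gc_fraction = ssr_gc
  )
}

#' Per-class SSR statistics for one genome
#'
#' Frequency, bases and density for every repeat class, zero-filled so the
#' result always has one row per class in the stable class order (501 rows
#' for `max_k = 6`).
#'
#' @inheritParams summarize_genome
#' @param genome_size Genome size in bp (including `N`s).
#' @param max_k Largest motif size, defining the class universe.
#' @return Tibble: `organism_id`, `repeat_class`, `frequency`, `bases`,
#'   `density` (bp/Mb), in stable class order.
#' @export
per_class_stats <- function(records, genome_size, organism_id, max_k = 6) {
  stopifnot(genome_size > 0)
  obs <- records |>
    dplyr::group_by(.data$repeat_class) |>
    dplyr::summarise(frequency = dplyr::n(), bases = sum(.data$length_bp),
                     .groups = "drop")
  tibble::tibble(repeat_class = class_order(max_k)) |>
    dplyr::left_join(obs, by = "repeat_class") |>
    dplyr::mutate(
      organism_id = organism_id,
      frequency = dplyr::coalesce(.data$frequency, 0L),
      bases = dplyr::coalesce(.data$bases, 0L),
      density = .data$bases / genome_size * 1e6
    ) |>
    dplyr::select("organism_id", "repeat_class", "frequency", "bases",
                  "density")
}

#' Assemble the cohort master table
#'
#' Joins per-organism genome summaries with the taxonomy columns of the
#' organism table, preserving the supplied (evolutionary) order.
#'
#' @param summaries Row-bound [summarize_genome()] results.
#' @param organisms Tibble with `organism_id`, `group`, `subgroup` (extra
#'   columns are carried through).
#' @return Tibble with one row per organism.
#' @export
master_table <- function(summaries, organisms) {
  missing <- setdiff(summaries$organism_id, organisms$organism_id)
  if (length(missing)) {
    stop("organisms absent from the organism table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  organisms |>
    dplyr::inner_join(summaries, by = "organism_id")
}
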