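# Repeat-length analytics: longest instances, unit-length histograms and
# length-preference peak detection.
#
# SSR abundance is expected to fall monotonically with repeat length. A
# length preference is a local rise in the abundance curve (count of SSRs at
# each exact complete-unit length) spanning at least 4 consecutive unit
# lengths with abundance > 10 at the peak start.

#' Longest repeat instances
#'
#' @param records SSR record tibble.
#' @param n Number of instances to keep (default 100; all if fewer exist).
#' @return Records sorted by `length_bp` descending (ties by `seq_id` then
#'   `start`), truncated to `n` rows.
#' @export
top_n_longest <- function(records, n = 100) {
  stopifnot(n >= 1)
  records |>
    dplyr::arrange(dplyr::desc(.data$length_bp), .data$seq_id, .data$start) |>
    utils::head(n)
}

#' Median length of the longest instances per class
#'
#' For each repeat class, the median `length_bp` over its up-to-`n` longest
#' instances. Classes absent from `records` are reported with `NA`.
#'
#' @param records SSR record tibble.
#' @param n Instances per class to consider (default 1000).
#' @param max_k Class universe for zero-filling.
#' @return Tibble `repeat_class`, `n_instances`, `median_length` in stable
#'   class order.
#' @export
class_length_medians <- function(records, n = 1000, max_k = 6) {
  stopifnot(n >= 1)
  obs <- records |>
    dplyr::group_by(.data$repeat_class) |>
    dplyr::arrange(dplyr::desc(.data$length_bp), .by_group = TRUE) |>
    dplyr::slice_head(n = n) |>
    dplyr::summarise(n_instances = dplyr::n(),
                     median_length = stats::median(.data$length_bp),
                     .groups = "drop")
  tibble::tibble(repeat_class = class_order(max_k)) |>
    dplyr::left_join(obs, by = "repeat_class") |>
    dplyr::mutate(n_instances = dplyr::coalesce(.data$n_instances, 0L))
}

#' Unit-length histogram per repeat class
#'
#' Counts SSRs at each complete-unit length (`units`), filling unobserved
#' unit lengths inside each class's observed range with zero so the
#' histogram is contiguous.
#'
#' @param records SSR record tibble (one organism).
#' @param organism_id Optional id column to attach.
#' @return Tibble `organism_id` (if given), `repeat_class`, `units`,
#'   `abundance`.
#' @export
unit_length_histogram <- function(records, organism_id = NULL) {
  h <- records |>
    dplyr::count(.data$repeat_class, .data$units, name = "abundance") |>
    dplyr::group_by(.data$repeat_class) |>
    tidyr::complete(units = tidyr::full_seq(.data$units, 1),
                    fill = list(abundance = 0L)) |>
    dplyr::ungroup() |>
    dplyr::mutate(units = as.integer(.data$units)) |>
    dplyr::arrange(.data$repeat_class, .data$units)
  if (!is.null(organism_id)) {
    h <- dplyr::mutate(h, organism_id = organism_id, .before = 1)
  }
  h
}

# Scan one contiguous abundance curve for preference peaks.
# units/abund: aligned vectors, units consecutive ascending.
scan_peaks <- function(units, abund, min_span = 4, min_start_abundance = 10) {
  n <- length(units)
  out <- list()
  i <- 1L
  while (i < n) {
    if (abund[i + 1L] > abund[i]) {
      # candidate peak starting at i (unit length before the first increase)
      e <- i + 1L
      while (e <= n && abund[e] >= abund[i]) e <- e + 1L
      if (e > n) break  # abundance never falls below the start: discard
      maxpos <- i + which.max(abund[(i + 1L):e])
      span <- units[e] - units[i] + 1L
      if (span >= min_span && abund[i] > min_start_abundance) {
        out[[length(out) + 1L]] <- tibble::tibble(
          peak_start = units[i], maxima = units[maxpos], end = units[e],
          span = span, start_abundance = abund[i],
          max_abundance = abund[maxpos]
        )
      }
      i <- e
    } else {
      i <- i + 1L
    }
  }
  dplyr::bind_rows(out)
}

#' Detect length-preference peaks in unit-length histograms
#'
#' Walks each class's abundance curve left to right. An increase between
#' consecutive unit lengths opens a candidate peak whose start is the unit
#' length before the first increase (plateaus do not count as an increase);
#' the curve must then reach a local maximum and decay, and the peak ends at
#' the first unit length where abundance drops strictly below the start
#' abundance. Candidates whose abundance never falls below the start before
#' the histogram ends are discarded. Reported peaks must span at least
#' `min_span` consecutive unit lengths (start and end included) and have
#' start abundance greater than `min_start_abundance`. Several disjoint
#' peaks per curve are allowed; scanning resumes after each peak's end.
#'
#' @param hist Tibble from [unit_length_histogram()] (optionally with an
#'   `organism_id` column, kept in the output).
#' @param min_span Minimum peak width in unit lengths (default 4).
#' @param min_start_abundance Required abundance at the peak start, strict
#'   (default 10).
#' @return Tibble of peaks: grouping columns plus `peak_start`, `maxima`,
#'   `end`, `span`, `start_abundance`, `max_abundance`. Zero rows when no
#'   curve qualifies.
#' @export
detect_length_preference <- function(hist, min_span = 4,
                                     min_start_abundance = 10) {
  if (nrow(hist) == 0) {
    return(tibble::tibble(repeat_class = character(), peak_start = integer(),
                          maxima = integer(), end = integer(),
                          span = integer(), start_abundance = integer(),
                          max_abundance = integer()))
  }
  grp <- intersect(c("organism_id", "repeat_class"), names(hist))
  hist |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "units")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) {
      if (any(diff(df$units) != 1L)) {
        stop("unit lengths must be contiguous; fill gaps with 0 ",
             "(see unit_length_histogram)", call. = FALSE)
      }
      scan_peaks(df$units, df$abundance, min_span, min_start_abundance)
    }) |>
    dplyr::ungroup()
}

#' Prevalence of length preference per subgroup
#'
#' Percentage of organisms within each subgroup showing a length preference
#' (at least one peak) for each repeat class. An organism counts once per
#' class regardless of how many peaks it has.
#'
#' @param peaks Peak tibble from [detect_length_preference()] with an
#'   `organism_id` column.
#' @param organisms Tibble mapping `organism_id` to `subgroup`.
#' @return Tibble `subgroup`, `repeat_class`, `n_with_preference`,
#'   `n_organisms`, `pct` in `[0, 100]`. Subgroup/class combinations with no
#'   preference are reported at 0 for classes that appear in `peaks`.
#' @export
preference_prevalence <- function(peaks, organisms) {
  stopifnot(all(c("organism_id", "subgroup") %in% names(organisms)))
  sizes <- dplyr::count(organisms, .data$subgroup, name = "n_organisms")
  if (nrow(peaks) == 0) {
    return(tibble::tibble(subgroup = character(), repeat_class = character(),
                          n_with_preference = integer(),
                          n_organisms = integer(), pct = numeric()))
  }
  unknown <- setdiff(unique(peaks$organism_id), organisms$organism_id)
  if (length(unknown)) {
    stop("unknown organism id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  peaks |>
    dplyr::distinct(.data$organism_id, .data$repeat_class) |>
    dplyr::inner_join(organisms[c("organism_id", "subgroup")],
                      by = "organism_id") |>
    dplyr::count(.data$subgroup, .data$repeat_class,
                 name = "n_with_preference") |>
    tidyr::complete(.data$subgroup, .data$repeat_class,
                    fill = list(n_with_preference = 0L)) |>
    dplyr::inner_join(sizes, by = "subgroup") |>
    dplyr::mutate(pct = 100 * .data$n_with_preference / .data$n_organisms)
}
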