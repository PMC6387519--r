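# Motif algebra: primitive 1-6 nt motifs and their canonical repeat classes.

.ssrscape_env <- new.env(parent = emptyenv())

#' Reverse complement of plain motif strings
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of reverse complements.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Test whether a motif is primitive
#'
#' A motif is primitive when it cannot be written as a shorter string repeated
#' in tandem: `"AAG"` is primitive, `"ACAC"` (= `"AC"` twice) is not. Only
#' primitive motifs name repeat classes; a poly-A run is a repeat of `"A"`,
#' never of `"AA"`.
#'
#' @param x Character vector of uppercase ACGT strings.
#' @return Logical vector, `TRUE` where the string is primitive.
#' @examples
#' is_primitive(c("AAG", "ACAC", "AAAAAA"))
#' @export
is_primitive <- function(x) {
  check_motif_alphabet(x)
  vapply(x, function(s) {
    k <- nchar(s)
    for (d in seq_len(k - 1)) {
      if (k %% d == 0 && strrep(substr(s, 1L, d), k %/% d) == s) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

check_motif_alphabet <- function(x) {
  if (length(x) == 0 || any(is.na(x)) || any(nchar(x) == 0)) {
    stop("motifs must be non-empty ACGT strings", call. = FALSE)
  }
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid motif (non-ACGT characters): ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

rotations <- function(s) {
  k <- nchar(s)
  if (k == 1L) return(s)
  i <- seq_len(k) - 1L
  paste0(substring(s, i + 1L, k), substring(s, 1L, i))
}

#' Canonical repeat class of a motif
#'
#' Collapses a primitive motif onto its repeat class representative: the
#' lexicographically smallest string among all cyclic rotations of the motif
#' and of its reverse complement. All motifs sharing a representative describe
#' the same tandem repeat read in either phase or strand, e.g. `"TTC"`,
#' `"TCT"`, `"GAA"` and `"AAG"` all map to class `"AAG"`.
#'
#' @param motif Character vector of primitive uppercase ACGT motifs
#'   (length 1-6 in ordinary use; any length is accepted).
#' @return Character vector of canonical class motifs, same length as input.
#'   Idempotent: `canonical_class(canonical_class(x))` equals
#'   `canonical_class(x)`.
#' @examples
#' canonical_class(c("TTC", "ACGT", "CTCGAG", "A"))
#' @export
canonical_class <- function(motif) {
  check_motif_alphabet(motif)
  prim <- is_primitive(motif)
  if (any(!prim)) {
    stop("non-primitive motif(s): ",
         paste(utils::head(motif[!prim], 3), collapse = ", "), call. = FALSE)
  }
  rc <- revcomp(motif)
  vapply(seq_along(motif), function(i) {
    min(c(rotations(motif[i]), rotations(rc[i])))
  }, character(1))
}

#' Enumerate all primitive DNA motifs up to a motif size
#'
#' Generates every string over \{A,C,G,T\} of length 1 to `max_k` that is not a
#' tandem repetition of a shorter string. For `max_k = 6` there are 5356 such
#' motifs (4, 12, 60, 240, 1020 and 4020 for k = 1..6).
#'
#' @param max_k Largest motif size, between 1 and 6.
#' @return Tibble with columns `motif` and `k`, sorted by `k` then motif.
#' @examples
#' nrow(enumerate_primitive_motifs(2)) # 16
#' @export
enumerate_primitive_motifs <- function(max_k = 6) {
  if (!is.numeric(max_k) || length(max_k) != 1 || max_k < 1 || max_k > 6) {
    stop("max_k must be a single integer in 1..6", call. = FALSE)
  }
  max_k <- as.integer(max_k)
  bases <- c("A", "C", "G", "T")
  purrr::map_dfr(seq_len(max_k), function(k) {
    all_k <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                             stringsAsFactors = FALSE)))
    all_k <- sort(all_k)
    tibble::tibble(motif = all_k[is_primitive(all_k)], k = k)
  })
}

#' GC fraction of the 12 bp tandem expansion of a motif
#'
#' GC content of a repeat class is evaluated on the 12 bp string formed by
#' repeating the motif in tandem (the minimum repeat length), not on the bare
#' motif. The two differ for pentamers, where the 12 bp window truncates the
#' third unit: `"AACGC"` expands to `"AACGCAACGCAA"`, GC = 5/12.
#'
#' @param motif Character vector of ACGT motifs.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_fraction_12bp <- function(motif) {
  check_motif_alphabet(motif)
  s12 <- substr(strrep(motif, ceiling(12 / nchar(motif))), 1L, 12L)
  stringr::str_count(s12, "[GC]") / 12
}

#' GC category of a repeat class
#'
#' Bins the 12 bp-expansion GC fraction into the five standard groups:
#' `LE25` (<= 25%), `GC26_49` (26-49%), `GC50` (exactly 50%), `GC51_74`
#' (51-74%) and `GE75` (>= 75%).
#'
#' @param motif Character vector of class motifs (or a precomputed GC
#'   fraction via `gc`).
#' @param gc Optional numeric vector of GC fractions; computed from `motif`
#'   when missing.
#' @return Factor with levels `LE25`, `GC26_49`, `GC50`, `GC51_74`, `GE75`.
#' @export
gc_category <- function(motif, gc = NULL) {
  if (is.null(gc)) gc <- gc_fraction_12bp(motif)
  out <- dplyr::case_when(
    gc <= 0.25 ~ "LE25",
    gc < 0.50  ~ "GC26_49",
    gc == 0.50 ~ "GC50",
    gc < 0.75  ~ "GC51_74",
    TRUE       ~ "GE75"
  )
  factor(out, levels = c("LE25", "GC26_49", "GC50", "GC51_74", "GE75"))
}

#' Enumerate canonical repeat classes
#'
#' Groups all primitive motifs of size 1 to `max_k` into repeat classes under
#' cyclic rotation and reverse complement. For `max_k = 6` this yields the 501
#' classes (2, 4, 10, 33, 102 and 350 for k = 1..6) that index every
#' downstream per-class table and score matrix; the row order here (k
#' ascending, then alphabetical) is the stable class order used throughout.
#'
#' @param max_k Largest motif size, between 1 and 6.
#' @return Tibble with one row per class: `canonical`, `k`, `orbit_size`
#'   (number of distinct primitive motifs collapsing onto the class),
#'   `gc_fraction` (on the 12 bp expansion) and `gc_category`.
#' @examples
#' classes <- enumerate_classes(2)
#' classes$canonical # "A" "C" "AC" "AG" "AT" "CG"
#' @export
enumerate_classes <- function(max_k = 6) {
  key <- paste0("classes_", max_k)
  if (!is.null(.ssrscape_env[[key]])) return(.ssrscape_env[[key]])
  motifs <- enumerate_primitive_motifs(max_k)
  out <- motifs |>
    dplyr::mutate(canonical = canonical_class(.data$motif)) |>
    dplyr::count(.data$canonical, .data$k, name = "orbit_size") |>
    dplyr::arrange(.data$k, .data$canonical) |>
    dplyr::mutate(
      gc_fraction = gc_fraction_12bp(.data$canonical),
      gc_category = gc_category(gc = .data$gc_fraction)
    ) |>
    dplyr::select("canonical", "k", "orbit_size", "gc_fraction", "gc_category")
  .ssrscape_env[[key]] <- out
  out
}

#' The stable class order for a given maximum motif size
#' @keywords internal
#' @noRd
class_order <- function(max_k = 6) enumerate_classes(max_k)$canonical

#' Write the repeat-class table to TSV
#'
#' @param classes Tibble from [enumerate_classes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_class_table <- function(classes, path) {
  readr::write_tsv(classes, path)
  invisible(path)
}
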