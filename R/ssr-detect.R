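# Exhaustive perfect tandem-repeat detection over genome sequences.
#
# A perfect SSR is a maximal run of a primitive 1-6 nt motif with no
# mismatches or indels, of total length >= min_length (default 12 bp, i.e.
# two complete units of the largest motif size). Coordinates follow the BED
# convention: 0-based, half-open.

empty_records <- function() {
  tibble::tibble(
    seq_id = character(), start = integer(), end = integer(),
    repeat_class = character(), actual_motif = character(),
    k = integer(), length_bp = integer(), units = integer()
  )
}

# divisors used for in-scan primitivity checks (proper divisors of each k)
.proper_divisors <- list(`1` = integer(0), `2` = 1L, `3` = 1L,
                         `4` = c(1L, 2L), `5` = 1L, `6` = c(1L, 2L, 3L))

#' Scan one sequence for perfect SSRs
#'
#' Finds maximal perfect tandem repeats of primitive motifs of size 1 to
#' `max_k` whose total length (including any partial trailing unit) is at
#' least `min_length`. Scanning is left-to-right greedy: at each position the
#' longest maximal perfect run starting there is taken (ties between motif
#' sizes go to the smaller motif), emitted if long enough, and scanning
#' resumes at its end, so emitted records never overlap. Runs are broken by
#' `N` and by sequence ends. Soft-masked (lowercase) sequence is uppercased
#' and scanned; IUPAC ambiguity codes other than `N` are treated as `N` with
#' a message; any other character is an error.
#'
#' @param sequence A single sequence as a character string (or anything
#'   coercible via `as.character`, e.g. a `DNAString`).
#' @param seq_id Sequence name to record.
#' @param min_length Minimum total repeat length in bp (default 12).
#' @param max_k Largest motif size to consider, 1-6 (default 6).
#' @return Tibble of SSR records sorted by `start`, with columns `seq_id`,
#'   `start`, `end` (0-based half-open), `repeat_class` (canonical motif),
#'   `actual_motif` (the motif as read at `start`), `k`, `length_bp` and
#'   `units` (complete motif copies, `length_bp %/% k`).
#' @examples
#' scan_sequence("ACACACACACAC")
#' @export
scan_sequence <- function(sequence, seq_id = "seq", min_length = 12,
                          max_k = 6) {
  stopifnot(length(sequence) == 1, min_length >= 2, max_k >= 1, max_k <= 6)
  min_length <- as.integer(min_length)
  max_k <- as.integer(max_k)
  s <- toupper(as.character(sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  amb <- chars %in% c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
  if (any(amb)) {
    message(sum(amb), " IUPAC ambiguity base(s) treated as N in ", seq_id)
    chars[amb] <- "N"
  }
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    stop("invalid character(s) in ", seq_id, ": ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  # split on N; scan each clean segment with its offset
  is_n <- chars == "N"
  if (all(is_n) || length(chars) < min_length) return(empty_records())
  r <- rle(is_n)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  keep <- !r$values & r$lengths >= min_length
  out <- purrr::map(which(keep), function(i) {
    scan_segment(chars[seg_start[i]:seg_end[i]], offset = seg_start[i] - 1L,
                 min_length = min_length, max_k = max_k)
  })
  recs <- dplyr::bind_rows(out)
  if (nrow(recs) == 0) return(empty_records())
  recs$seq_id <- seq_id
  recs |>
    dplyr::arrange(.data$start) |>
    dplyr::select("seq_id", "start", "end", "repeat_class", "actual_motif",
                  "k", "length_bp", "units")
}

# Core scanner on an N-free character vector. For each period k it
# vectorises runlen[i] = number of consecutive positions from i with
# chars[i+j] == chars[i+j+k], via a next-mismatch cummin scan; the maximal
# k-periodic run starting at i then has length runlen[i] + k. Primitivity of
# the motif at (i, k) is equivalent to runlen_d[i] < k - d for every proper
# divisor d of k.
scan_segment <- function(chars, offset, min_length, max_k) {
  n <- length(chars)
  ks <- seq_len(min(max_k, n %/% 2L))
  runlen <- vector("list", max(ks))
  for (k in ks) {
    m <- n - k
    match_k <- chars[seq_len(m)] == chars[(k + 1L):n]
    pos <- seq_len(m)
    next_mm <- rev(cummin(rev(ifelse(match_k, m + 1L, pos))))
    runlen[[k]] <- c(next_mm - pos, rep(0L, k))  # pad so length == n
  }
  best_len <- integer(n)
  best_k <- integer(n)
  for (k in rev(ks)) {            # descending, so smaller k wins ties via >=
    len_k <- runlen[[k]] + k
    ok <- len_k >= min_length & runlen[[k]] > 0L
    for (d in .proper_divisors[[k]]) {
      ok <- ok & runlen[[d]] < (k - d)    # primitive motif at this position
    }
    upd <- ok & len_k >= best_len
    best_len[upd] <- len_k[upd]
    best_k[upd] <- k
  }
  cand <- which(best_k > 0L)
  if (length(cand) == 0) return(empty_records())
  starts <- integer(length(cand)); lens <- integer(length(cand))
  ksel <- integer(length(cand)); m <- 0L; cur <- 0L
  for (i in cand) {
    if (i < cur) next
    m <- m + 1L
    starts[m] <- i; lens[m] <- best_len[i]; ksel[m] <- best_k[i]
    cur <- i + best_len[i]
  }
  starts <- starts[seq_len(m)]; lens <- lens[seq_len(m)]
  ksel <- ksel[seq_len(m)]
  seq_str <- paste(chars, collapse = "")
  motifs <- substring(seq_str, starts, starts + ksel - 1L)
  tibble::tibble(
    seq_id = NA_character_,
    start = offset + starts - 1L,
    end = offset + starts - 1L + lens,
    repeat_class = canonical_class(motifs),
    actual_motif = motifs,
    k = ksel,
    length_bp = lens,
    units = lens %/% ksel
  )
}

#' Scan a FASTA file for perfect SSRs
#'
#' Runs [scan_sequence()] over every record of a (plain or gzipped) FASTA
#' file and collects per-sequence statistics.
#'
#' @inheritParams scan_sequence
#' @param fasta_path Path to the FASTA file.
#' @return List with two tibbles: `records` (all SSR records, in file order)
#'   and `sequences` (`seq_id`, `length_bp`, `gc_fraction` of non-N bases,
#'   `n_count`).
#' @export
scan_fasta <- function(fasta_path, min_length = 12, max_k = 6) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop("empty FASTA: ", fasta_path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(ids) | ids == "")) {
    stop("missing sequence id in ", fasta_path, call. = FALSE)
  }
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  widths <- Biostrings::width(seqs)
  acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
  non_n <- rowSums(acgt)
  stats <- tibble::tibble(
    seq_id = ids,
    length_bp = as.integer(widths),
    gc_fraction = ifelse(non_n > 0,
                         (acgt[, "C"] + acgt[, "G"]) / non_n, NA_real_),
    n_count = as.integer(widths - non_n)
  )
  records <- purrr::map2(as.character(seqs), ids, function(s, id) {
    scan_sequence(s, seq_id = id, min_length = min_length, max_k = max_k)
  })
  records <- dplyr::bind_rows(records)
  if (nrow(records) == 0) records <- empty_records()
  list(records = records, sequences = stats)
}

#' Write SSR records as BED6+ TSV
#'
#' Columns, in order: `seq_id`, `start`, `end`, `repeat_class`, `length_bp`,
#' `strand` (always `"+"`), `actual_motif`, `units`. No header is written
#' (BED convention).
#'
#' @param records SSR record tibble from [scan_sequence()]/[scan_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_bed <- function(records, path) {
  bed <- records |>
    dplyr::transmute(.data$seq_id, .data$start, .data$end, .data$repeat_class,
                     .data$length_bp, strand = "+", .data$actual_motif,
                     .data$units)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
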