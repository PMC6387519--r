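# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation: character-by-
# character walks and explicit orbit/agglomeration enumeration.

# --- reference SSR finder: per-position char-walk extension + greedy ------

oracle_primitive <- function(motif_chars) {
  k <- length(motif_chars)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 &&
        all(motif_chars == motif_chars[((seq_len(k) - 1) %% d) + 1])) {
      return(FALSE)
    }
  }
  TRUE
}

oracle_scan <- function(sequence, seq_id = "seq", min_length = 12,
                        max_k = 6) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  recs <- list()
  seg_start <- 1L
  emit_segment <- function(lo, hi) {
    i <- lo
    while (i <= hi) {
      best_len <- 0L
      best_k <- 0L
      for (k in seq_len(max_k)) {
        if (i + k - 1L > hi) break
        if (!oracle_primitive(chars[i:(i + k - 1L)])) next
        j <- i + k
        while (j <= hi && chars[j] == chars[j - k]) j <- j + 1L
        L <- j - i
        if (L >= min_length && L > best_len) {
          best_len <- L
          best_k <- k
        }
      }
      if (best_len > 0L) {
        recs[[length(recs) + 1L]] <<- data.frame(
          seq_id = seq_id, start = i - 1L, end = i - 1L + best_len,
          actual_motif = paste(chars[i:(i + best_k - 1L)], collapse = ""),
          k = best_k, length_bp = best_len, units = best_len %/% best_k,
          stringsAsFactors = FALSE)
        i <- i + best_len
      } else {
        i <- i + 1L
      }
    }
  }
  is_n <- chars == "N"
  i <- 1L
  while (i <= n) {
    if (is_n[i]) {
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !is_n[j]) j <- j + 1L
    emit_segment(i, j - 1L)
    i <- j
  }
  if (length(recs) == 0) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), actual_motif = character(),
                      k = integer(), length_bp = integer(),
                      units = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

# --- brute-force orbit enumeration of repeat classes ----------------------

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, ""), function(ch) {
           paste(rev(ch), collapse = "")
         }, character(1)))
}

oracle_rotations <- function(s) {
  k <- nchar(s)
  vapply(seq_len(k) - 1L, function(i) {
    paste0(substr(s, i + 1, k), substr(s, 1, i))
  }, character(1))
}

# all classes for exactly motif size k, via explicit orbit grouping of the
# full 4^k string set (non-primitive strings dropped by orbit inspection)
oracle_classes_k <- function(k) {
  bases <- c("A", "C", "G", "T")
  all_k <- sort(do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                                stringsAsFactors = FALSE))))
  prim <- vapply(all_k, function(s) {
    oracle_primitive(strsplit(s, "")[[1]])
  }, logical(1))
  all_k <- all_k[prim]
  seen <- character(0)
  classes <- list()
  for (s in all_k) {
    if (s %in% seen) next
    orbit <- unique(c(oracle_rotations(s), oracle_rotations(oracle_revcomp(s))))
    orbit <- intersect(orbit, all_k)
    seen <- c(seen, orbit)
    classes[[length(classes) + 1L]] <- data.frame(
      canonical = min(orbit), orbit_size = length(orbit),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, classes)
  out[order(out$canonical), , drop = FALSE]
}

# --- O(n^3) average-linkage agglomeration on matrix columns ---------------

ref_average_linkage <- function(X) {
  d <- as.matrix(stats::dist(t(X)))
  clusters <- as.list(seq_len(ncol(X)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        h <- mean(d[clusters[[a]], clusters[[b]]])
        if (h < best_h) {
          best_h <- h
          best <- c(a, b)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    part <- integer(ncol(X))
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# --- misc helpers ---------------------------------------------------------

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_primitive_motif <- function(k) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
               collapse = "")
    if (is_primitive(m)) return(m)
  }
}

expect_same_records <- function(records, oracle) {
  df <- as.data.frame(records[c("seq_id", "start", "end", "actual_motif",
                                "k", "length_bp", "units")])
  or <- as.data.frame(oracle[c("seq_id", "start", "end", "actual_motif",
                               "k", "length_bp", "units")])
  rownames(df) <- rownames(or) <- NULL
  expect_equal(df, or)
}

make_hist <- function(counts, repeat_class = "AGAT") {
  tibble::tibble(repeat_class = repeat_class,
                 units = as.integer(names(counts)),
                 abundance = as.integer(unname(counts)))
}
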