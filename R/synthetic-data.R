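# Synthetic genomes, annotations and cohorts with planted ground truth.
#
# The generator builds genomes whose background is repeat-free at the
# detection threshold, with perfect repeat arrays planted at known positions,
# so the detector's output can be compared against an exact truth table.
# Cohorts add the cross-organism structure the comparative analyses assume:
# a shared baseline repeat landscape with noise, clade-specific signature
# classes, and unit-length abundance bumps for length-preference recovery.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic genome
#'
#' @param organism_id Organism identifier.
#' @param genome_length Genome length in bp.
#' @param background_gc GC fraction of the background sequence.
#' @param seed Integer seed; the genome is deterministic given the spec.
#' @param planted_repeats Tibble with columns `motif` (primitive ACGT motif,
#'   as it should read at the repeat start), one of `units` or `length_bp`,
#'   and optionally `start` (0-based; `NA` = placed at random without
#'   overlap, separated by at least 3 background bases).
#' @param gene_models Optional tibble of toy gene models: `gene_id`, `start`,
#'   `end` (1-based inclusive), `strand`, and `exons`, a list-column of
#'   data frames with `start`/`end`. `NULL` for no annotation.
#' @param group,subgroup Taxonomy labels carried into cohort manifests.
#' @return A `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(organism_id, genome_length = 200000,
                                  background_gc = 0.41, seed = 1,
                                  planted_repeats = NULL, gene_models = NULL,
                                  group = NA_character_,
                                  subgroup = NA_character_) {
  if (is.null(planted_repeats)) {
    planted_repeats <- tibble::tibble(motif = character(), units = integer(),
                                      start = integer())
  }
  planted_repeats <- tibble::as_tibble(planted_repeats)
  if (nrow(planted_repeats) > 0) {
    check_motif_alphabet(planted_repeats$motif)
    if (!all(is_primitive(planted_repeats$motif))) {
      stop("planted motifs must be primitive", call. = FALSE)
    }
    if (!"start" %in% names(planted_repeats)) planted_repeats$start <- NA
    if (!"length_bp" %in% names(planted_repeats)) {
      planted_repeats$length_bp <-
        planted_repeats$units * nchar(planted_repeats$motif)
    }
    if (any(is.na(planted_repeats$length_bp))) {
      stop("planted repeats need units or length_bp", call. = FALSE)
    }
  } else {
    planted_repeats$length_bp <- integer()
  }
  structure(list(organism_id = organism_id,
                 genome_length = as.integer(genome_length),
                 background_gc = background_gc, seed = as.integer(seed),
                 planted_repeats = planted_repeats,
                 gene_models = gene_models, group = group,
                 subgroup = subgroup),
            class = "synthetic_genome_spec")
}

expand_repeat <- function(motif, length_bp) {
  substr(strrep(motif, ceiling(length_bp / nchar(motif))), 1L, length_bp)
}

# place arrays left unplaced by the spec: uniform rejection sampling with a
# minimum gap of 3 background bases between arrays and to sequence ends
place_repeats <- function(planted, genome_length) {
  lens <- planted$length_bp
  starts <- suppressWarnings(as.integer(planted$start))
  occ <- matrix(numeric(0), ncol = 2)  # occupied [start, end) + gap
  add_occ <- function(s, l) rbind(occ, c(s - 3L, s + l + 3L))
  for (i in order(is.na(starts))) {    # fixed positions first
    if (!is.na(starts[i])) {
      occ <- add_occ(starts[i], lens[i])
      next
    }
    for (try in 1:10000) {
      s <- sample.int(genome_length - lens[i] - 6L, 1L) + 2L
      if (nrow(occ) == 0 ||
          all(s + lens[i] <= occ[, 1] | s >= occ[, 2])) {
        starts[i] <- s
        occ <- add_occ(s, lens[i])
        break
      }
    }
    if (is.na(starts[i])) {
      stop("could not place planted repeats without overlap; genome too ",
           "dense", call. = FALSE)
    }
  }
  ord <- order(starts)
  planted$start <- starts
  planted <- planted[ord, , drop = FALSE]
  if (nrow(planted) > 1) {
    gap <- planted$start[-1] -
      (planted$start[-nrow(planted)] + planted$length_bp[-nrow(planted)])
    if (any(gap < 1)) stop("planted repeats overlap", call. = FALSE)
  }
  if (any(planted$start < 0 |
          planted$start + planted$length_bp > genome_length)) {
    stop("planted repeat exceeds genome bounds", call. = FALSE)
  }
  planted
}

# enforce that no planted array can be extended by one base on either side
apply_boundary_pads <- function(chars, planted) {
  n <- length(chars)
  for (i in seq_len(nrow(planted))) {
    k <- nchar(planted$motif[i])
    a <- planted$start[i] + 1L           # 1-based first base
    b <- planted$start[i] + planted$length_bp[i]
    if (a > 1L && chars[a - 1L] == chars[a - 1L + k]) {
      chars[a - 1L] <- setdiff(c("A", "C", "G", "T"),
                               c(chars[a - 1L + k], chars[a - 2L][a > 2L]))[1]
    }
    if (b < n && chars[b + 1L] == chars[b + 1L - k]) {
      chars[b + 1L] <- setdiff(c("A", "C", "G", "T"),
                               c(chars[b + 1L - k],
                                 chars[b + 2L][b + 1L < n]))[1]
    }
  }
  chars
}

#' Generate a synthetic genome with planted repeats
#'
#' Builds an i.i.d. background at the requested GC, inserts the planted
#' arrays verbatim, pads their boundaries so each is exactly maximal, and
#' then repeatedly rescans the sequence, breaking any incidental background
#' repeat at the detection threshold by substitution, until the detector's
#' output equals the truth table exactly. Deterministic given the spec.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param min_length,max_k Detection settings the background is cleaned
#'   against (defaults 12 and 6).
#' @return List: `organism_id`, `sequence` (character string), `truth`
#'   (SSR record tibble the detector must reproduce), `gff` (GFF3 text lines
#'   or `NULL`) and `spec`.
#' @export
generate_genome <- function(spec, min_length = 12, max_k = 6) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  local_seed(spec$seed, {
    gc <- spec$background_gc
    chars <- sample(c("A", "C", "G", "T"), spec$genome_length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    planted <- spec$planted_repeats
    if (nrow(planted) > 0) {
      planted <- place_repeats(planted, spec$genome_length)
      protected <- logical(spec$genome_length)
      for (i in seq_len(nrow(planted))) {
        idx <- (planted$start[i] + 1L):(planted$start[i] +
                                          planted$length_bp[i])
        chars[idx] <- strsplit(expand_repeat(planted$motif[i],
                                             planted$length_bp[i]),
                               "")[[1]]
        protected[idx] <- TRUE
      }
      pads <- unique(c(planted$start, planted$start + planted$length_bp + 1L))
      pads <- pads[pads >= 1 & pads <= spec$genome_length]
      protected[pads] <- TRUE   # pads fixed by constraint, not perturbed
    } else {
      planted <- planted
      protected <- logical(spec$genome_length)
    }
    seq_id <- paste0(spec$organism_id, "_chr1")
    truth <- if (nrow(planted) > 0) {
      tibble::tibble(
        seq_id = seq_id,
        start = as.integer(planted$start),
        end = as.integer(planted$start + planted$length_bp),
        repeat_class = canonical_class(planted$motif),
        actual_motif = planted$motif,
        k = nchar(planted$motif),
        length_bp = as.integer(planted$length_bp),
        units = as.integer(planted$length_bp %/% nchar(planted$motif))
      )
    } else empty_records()
    truth <- truth[truth$length_bp >= min_length, , drop = FALSE]
    for (iter in 1:200) {
      if (nrow(planted) > 0) chars <- apply_boundary_pads(chars, planted)
      det <- scan_sequence(paste(chars, collapse = ""), seq_id = seq_id,
                           min_length = min_length, max_k = max_k)
      key <- function(d) paste(d$start, d$end, d$actual_motif)
      extra <- det[!(key(det) %in% key(truth)), , drop = FALSE]
      missing <- truth[!(key(truth) %in% key(det)), , drop = FALSE]
      if (nrow(extra) == 0 && nrow(missing) == 0) break
      bad <- rbind(extra[c("start", "end")], missing[c("start", "end")])
      for (j in seq_len(nrow(bad))) {
        idx <- (bad$start[j] + 1L):bad$end[j]
        idx <- pmax(pmin(idx, spec$genome_length), 1L)
        idx <- idx[!protected[idx]]
        if (length(idx) == 0) next
        p <- if (length(idx) == 1) idx else sample(idx, 1L)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      if (iter == 200) stop("background could not be made repeat-free",
                            call. = FALSE)
    }
    gff <- if (!is.null(spec$gene_models)) {
      gene_models_gff(spec$gene_models, seq_id)
    } else NULL
    list(organism_id = spec$organism_id, sequence = paste(chars, collapse = ""),
         truth = truth, gff = gff, spec = spec)
  })
}

gene_models_gff <- function(gm, seq_id) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(gm))) {
    lines <- c(lines, paste(seq_id, "ssrscape", "gene", gm$start[i],
                            gm$end[i], ".", gm$strand[i], ".",
                            paste0("ID=", gm$gene_id[i]), sep = "\t"))
    ex <- gm$exons[[i]]
    for (j in seq_len(NROW(ex))) {
      lines <- c(lines, paste(seq_id, "ssrscape", "exon", ex$start[j],
                              ex$end[j], ".", gm$strand[i], ".",
                              paste0("ID=", gm$gene_id[i], ".e", j,
                                     ";Parent=", gm$gene_id[i]), sep = "\t"))
    }
  }
  lines
}

#' Write a generated genome to disk
#'
#' @param genome Output of [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return Tibble with `organism_id`, `fasta`, `gff` (`NA` if no gene
#'   models) and `truth` paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(genome$organism_id, ".fa"))
  writeLines(c(paste0(">", genome$organism_id, "_chr1"),
               substring(genome$sequence,
                         seq(1, nchar(genome$sequence), 70),
                         pmin(seq(1, nchar(genome$sequence), 70) + 69,
                              nchar(genome$sequence)))), fa)
  gff <- NA_character_
  if (!is.null(genome$gff)) {
    gff <- file.path(dir, paste0(genome$organism_id, ".gff3"))
    writeLines(genome$gff, gff)
  }
  truth_path <- file.path(dir, paste0(genome$organism_id, "_truth.tsv"))
  readr::write_tsv(genome$truth, truth_path)
  tibble::tibble(organism_id = genome$organism_id, fasta = fa, gff = gff,
                 truth = truth_path)
}

# deterministic baseline repeat landscape: class i of the ladder has
# expected instance count ratio^(i-1) * count0, with lognormal noise per
# organism, so per-organism top-10 sets are stable across the cohort
baseline_plan <- function(baseline_classes, count0, ratio) {
  tibble::tibble(
    repeat_class = baseline_classes,
    expected_count = count0 * ratio^(seq_along(baseline_classes) - 1)
  )
}

sample_baseline_repeats <- function(plan, noise_sd = 0.2) {
  purrr::pmap_dfr(plan, function(repeat_class, expected_count) {
    n <- stats::rpois(1, expected_count * stats::rlnorm(1, 0, noise_sd))
    if (n == 0) return(NULL)
    k <- nchar(repeat_class)
    min_units <- ceiling(12 / k)
    units <- min_units + stats::rgeom(n, 0.35)
    tibble::tibble(motif = repeat_class, units = units)
  })
}

#' Generate a multi-organism synthetic cohort
#'
#' Every organism shares a deterministic baseline repeat landscape (a
#' geometric ladder of expected instance counts over `n_baseline` classes,
#' with per-organism lognormal noise). Clades listed in `clades` additionally
#' carry their signature class at high copy number (roughly
#' `signature_fold` times the median baseline class coverage) while
#' non-members carry at most a trace (< 10 instances); organisms in
#' `peak_plan` receive extra instances of a class whose unit-length counts
#' form a bump on top of a decaying baseline curve.
#'
#' @param n_organisms Number of organisms.
#' @param subgroups Character vector (length `n_organisms`) of subgroup
#'   labels; defaults to `"sg1"`... split in 3.
#' @param clades Named list mapping clade name to organism indices
#'   (1-based) or ids `org01`, ...
#' @param signature_classes Named character vector: clade name -> class
#'   motif. Must be distinct across clades and outside the baseline ladder.
#' @param signature_fold Density fold of the signature class relative to the
#'   median baseline class (default 10).
#' @param peak_plan Tibble: `organism` (index or id), `repeat_class`,
#'   `bump_start` (unit length), `bump_width` (>= 1), `bump_height`
#'   (added abundance per unit length).
#' @param genome_length,background_gc Per-genome parameters.
#' @param n_baseline,count0,ratio Baseline ladder parameters: number of
#'   classes, expected count of the most abundant one, decay ratio.
#' @param seed Cohort seed; per-organism seeds are derived from it.
#' @return List: `specs` (list of [synthetic_genome_spec()]), `manifest`
#'   (tibble `organism_id`, `group`, `subgroup`, `order`, `seed`), and
#'   `truth` (list with `signatures` and `peaks` tibbles).
#' @export
generate_cohort <- function(n_organisms = 12, subgroups = NULL,
                            clades = NULL, signature_classes = NULL,
                            signature_fold = 10, peak_plan = NULL,
                            genome_length = 150000, background_gc = 0.41,
                            n_baseline = 25, count0 = 60, ratio = 0.82,
                            seed = 1) {
  ids <- sprintf("org%02d", seq_len(n_organisms))
  if (is.null(subgroups)) {
    subgroups <- paste0("sg", rep(1:3, length.out = n_organisms) |> sort())
  }
  stopifnot(length(subgroups) == n_organisms)
  norm_ids <- function(x) if (is.numeric(x)) ids[x] else x
  clades <- purrr::map(clades, norm_ids)
  if (!is.null(signature_classes)) {
    if (anyDuplicated(signature_classes)) {
      stop("signature classes must be unique across clades", call. = FALSE)
    }
    stopifnot(!is.null(clades), all(names(signature_classes) %in%
                                      names(clades)))
  }
  local_seed(seed, {
    org_seeds <- sample.int(.Machine$integer.max - 1L, n_organisms)
    # deterministic ladder classes: abundant, AT-rich, away from signatures
    universe <- enumerate_classes(6)$canonical
    avoid <- unique(c(signature_classes,
                      if (!is.null(peak_plan)) peak_plan$repeat_class))
    ladder <- setdiff(c("A", "AC", "AG", "AT", "C", "AAT", "AAG", "AAC",
                        "AGG", "ACC", "AGAT", "AAAT", "AAAG", "ACAT",
                        "AATG", "AAAAT", "AAAAC", "AACCT", "AAAAG",
                        "AATAG", "AAAAAT", "AAAAAC", "AATAAG", "AAATAG",
                        "ACATAT", "AAACTG", "AAGATG", "ACCTCC", "AATTGG",
                        "ACGTAC"), avoid)[seq_len(n_baseline)]
    plan <- baseline_plan(ladder, count0, ratio)
    med_cov <- stats::median(plan$expected_count *
                               ceiling(12 / nchar(plan$repeat_class)) * 1.5 *
                               nchar(plan$repeat_class))
    specs <- purrr::map(seq_len(n_organisms), function(i) {
      local_seed(org_seeds[i], {
        rep_tbl <- sample_baseline_repeats(plan)
        for (cn in names(clades)) {
          cls <- signature_classes[[cn]]
          if (is.null(cls) || is.na(cls)) next
          k <- nchar(cls)
          if (ids[i] %in% clades[[cn]]) {
            units <- ceiling(12 / k) + stats::rgeom(
              max(20L, ceiling(signature_fold * med_cov /
                                 (ceiling(12 / k) * k * 1.4))), 0.35)
            rep_tbl <- dplyr::bind_rows(rep_tbl,
                                        tibble::tibble(motif = cls,
                                                       units = units))
          } else {
            n_trace <- stats::rpois(1, 1.5)  # < 10 instances, never top-10
            if (n_trace > 0) {
              rep_tbl <- dplyr::bind_rows(
                rep_tbl, tibble::tibble(motif = cls,
                                        units = rep(ceiling(12 / k),
                                                    n_trace)))
            }
          }
        }
        if (!is.null(peak_plan)) {
          pp <- peak_plan
          pp$organism <- norm_ids(pp$organism)
          pp <- pp[pp$organism == ids[i], , drop = FALSE]
          for (j in seq_len(nrow(pp))) {
            rep_tbl <- dplyr::bind_rows(
              rep_tbl, bump_repeats(pp$repeat_class[j], pp$bump_start[j],
                                    pp$bump_width[j], pp$bump_height[j]))
          }
        }
        synthetic_genome_spec(
          organism_id = ids[i], genome_length = genome_length,
          background_gc = background_gc, seed = org_seeds[i],
          planted_repeats = rep_tbl,
          group = "synthetic", subgroup = subgroups[i])
      })
    })
    truth <- list(
      signatures = if (is.null(signature_classes)) {
        tibble::tibble(clade_name = character(), repeat_class = character())
      } else {
        tibble::tibble(clade_name = names(signature_classes),
                       repeat_class = unname(signature_classes))
      },
      peaks = if (is.null(peak_plan)) {
        tibble::tibble(organism_id = character(), repeat_class = character())
      } else {
        tibble::tibble(organism_id = norm_ids(peak_plan$organism),
                       repeat_class = peak_plan$repeat_class,
                       bump_start = peak_plan$bump_start,
                       bump_width = peak_plan$bump_width)
      }
    )
    list(specs = specs,
         manifest = tibble::tibble(organism_id = ids, group = "synthetic",
                                   subgroup = subgroups,
                                   order = seq_len(n_organisms),
                                   seed = org_seeds),
         truth = truth)
  })
}

# unit-length counts for a planted preference peak: a decaying baseline
# curve (so abundance falls monotonically outside the bump) plus a flat bump
# of `height` extra instances per unit length over the bump window
bump_repeats <- function(repeat_class, bump_start, bump_width, bump_height,
                         base0 = 220, base_ratio = 0.72) {
  k <- nchar(repeat_class)
  min_units <- ceiling(12 / k)
  max_units <- bump_start + bump_width + 2L
  units_range <- min_units:max_units
  counts <- pmax(round(base0 * base_ratio^(units_range - min_units)), 0)
  in_bump <- units_range >= bump_start & units_range < bump_start + bump_width
  counts[in_bump] <- counts[in_bump] + bump_height
  tibble::tibble(motif = repeat_class,
                 units = rep(units_range, counts))
}

#' Materialise a cohort on disk
#'
#' Generates every genome of a [generate_cohort()] plan and writes FASTA,
#' GFF3 (when gene models are present), per-genome truth tables and a
#' cohort manifest TSV.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory.
#' @return The manifest tibble, augmented with `fasta`, `gff` and `truth`
#'   paths (also written to `dir/manifest.tsv`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_dfr(cohort$specs, function(sp) {
    write_genome(generate_genome(sp), dir)
  })
  manifest <- dplyr::left_join(cohort$manifest, paths, by = "organism_id")
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}

#' Simulate per-class statistics for a cohort without sequence realisation
#'
#' Draws per-organism, per-class densities directly from the cohort's
#' density model (baseline ladder + clade signatures), for replicate-heavy
#' statistical checks where generating and scanning full genomes would be
#' wasteful. The model matches what [generate_cohort()] plants: identical
#' ladder, noise and signature fold, converted to bases over the same
#' genome length.
#'
#' @inheritParams generate_cohort
#' @return Row-bound [per_class_stats()]-shaped tibble for all organisms.
#' @export
simulate_class_stats <- function(n_organisms = 12, clades = NULL,
                                 signature_classes = NULL,
                                 signature_fold = 10,
                                 genome_length = 150000, n_baseline = 25,
                                 count0 = 60, ratio = 0.82, seed = 1) {
  ids <- sprintf("org%02d", seq_len(n_organisms))
  norm_ids <- function(x) if (is.numeric(x)) ids[x] else x
  clades <- purrr::map(clades, norm_ids)
  local_seed(seed, {
    avoid <- unique(unname(signature_classes))
    ladder <- setdiff(c("A", "AC", "AG", "AT", "C", "AAT", "AAG", "AAC",
                        "AGG", "ACC", "AGAT", "AAAT", "AAAG", "ACAT",
                        "AATG", "AAAAT", "AAAAC", "AACCT", "AAAAG",
                        "AATAG", "AAAAAT", "AAAAAC", "AATAAG", "AAATAG",
                        "ACATAT", "AAACTG", "AAGATG", "ACCTCC", "AATTGG",
                        "ACGTAC"), avoid)[seq_len(n_baseline)]
    plan <- baseline_plan(ladder, count0, ratio)
    mean_len <- ceiling(12 / nchar(plan$repeat_class)) *
      nchar(plan$repeat_class) * 1.4
    med_cov <- stats::median(plan$expected_count * mean_len)
    purrr::map_dfr(ids, function(id) {
      counts <- stats::rpois(nrow(plan),
                             plan$expected_count * stats::rlnorm(
                               nrow(plan), 0, 0.2))
      bases <- round(counts * mean_len)
      stats_one <- tibble::tibble(repeat_class = plan$repeat_class,
                                  frequency = counts, bases = bases)
      for (cn in names(clades)) {
        cls <- signature_classes[[cn]]
        if (is.null(cls) || is.na(cls)) next
        if (id %in% clades[[cn]]) {
          b <- round(signature_fold * med_cov * stats::rlnorm(1, 0, 0.15))
          f <- max(20L, round(b / (nchar(cls) * 3)))
        } else {
          f <- stats::rpois(1, 1.5)
          b <- f * 12L
        }
        stats_one <- dplyr::bind_rows(
          stats_one, tibble::tibble(repeat_class = cls,
                                    frequency = as.integer(f),
                                    bases = as.numeric(b)))
      }
      tibble::tibble(repeat_class = class_order(6)) |>
        dplyr::left_join(stats_one, by = "repeat_class") |>
        dplyr::mutate(organism_id = id,
                      frequency = dplyr::coalesce(.data$frequency, 0L),
                      bases = dplyr::coalesce(.data$bases, 0),
                      density = .data$bases / genome_length * 1e6) |>
        dplyr::select("organism_id", "repeat_class", "frequency", "bases",
                      "density")
    })
  })
}

#' Random toy gene models
#'
#' Lays out `n_genes` equally sized genes with two exons each along a
#' genome, alternating strand, for annotation tests.
#'
#' @param genome_length Genome length in bp.
#' @param n_genes Number of genes.
#' @param gene_fraction Fraction of the genome covered by gene bodies.
#' @return Gene-model tibble accepted by [synthetic_genome_spec()].
#' @export
random_gene_models <- function(genome_length, n_genes = 5,
                               gene_fraction = 0.4) {
  span <- floor(genome_length * gene_fraction / n_genes)
  pitch <- floor(genome_length / n_genes)
  purrr::map_dfr(seq_len(n_genes), function(i) {
    g_start <- (i - 1L) * pitch + floor((pitch - span) / 2)
    g_end <- g_start + span - 1L
    exon_len <- floor(span / 4)
    tibble::tibble(
      gene_id = sprintf("gene%02d", i),
      start = g_start, end = g_end,
      strand = if (i %% 2 == 1) "+" else "-",
      exons = list(data.frame(
        start = c(g_start, g_end - exon_len + 1L),
        end = c(g_start + exon_len - 1L, g_end)))
    )
  })
}
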