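# Rank-based enrichment scoring across organisms, class clustering, and
# clade-signature tests.
#
# Within each organism all repeat classes are ranked by density (rank 1 =
# densest). Scores: 3 for ranks 1-10, 2 for 11-25, 1 for 26-100, -1 for the
# bottom 100 ranks (402-501 of the full ranking) when frequency >= 10, 0
# otherwise; any class with frequency < 10 scores -2 regardless of rank, to
# damp sampling noise from near-absent classes.

#' Rank repeat classes of one organism by density
#'
#' Deterministic ranking: density descending, ties broken by frequency
#' descending, then canonical motif alphabetically.
#'
#' @param class_stats Per-class tibble for one organism
#'   ([per_class_stats()] output).
#' @return Integer ranks aligned with the rows of `class_stats`.
#' @export
rank_classes <- function(class_stats) {
  ord <- order(-class_stats$density, -class_stats$frequency,
               class_stats$repeat_class)
  rk <- integer(nrow(class_stats))
  rk[ord] <- seq_len(nrow(class_stats))
  rk
}

#' Enrichment scores for one organism
#'
#' @inheritParams rank_classes
#' @return Tibble `repeat_class`, `rank`, `score` (score in \{-2,-1,0,1,2,3\}),
#'   in the row order of `class_stats`.
#' @export
score_organism <- function(class_stats) {
  n <- nrow(class_stats)
  rk <- rank_classes(class_stats)
  score <- integer(n)
  score[rk <= 100] <- 1L
  score[rk <= 25] <- 2L
  score[rk <= 10] <- 3L
  score[rk > n - 100] <- -1L
  score[class_stats$frequency < 10] <- -2L
  tibble::tibble(repeat_class = class_stats$repeat_class, rank = rk,
                 score = score)
}

#' Build the organisms x classes score matrix
#'
#' @param class_stats_all Row-bound [per_class_stats()] tibbles for a cohort.
#' @param organism_order Optional character vector fixing the row
#'   (evolutionary) order; defaults to order of first appearance.
#' @return An `ssr_score_matrix`: list with integer `scores`
#'   (organisms x classes), `organisms` and `classes`. Columns follow the
#'   stable class order.
#' @export
build_score_matrix <- function(class_stats_all, organism_order = NULL) {
  if (is.null(organism_order)) {
    organism_order <- unique(class_stats_all$organism_id)
  }
  if (anyDuplicated(organism_order)) {
    stop("duplicate organism ids", call. = FALSE)
  }
  stopifnot(length(organism_order) >= 1)
  classes <- enumerate_classes(6)$canonical
  classes <- classes[classes %in% unique(class_stats_all$repeat_class)]
  per_org <- class_stats_all |>
    dplyr::group_by(.data$organism_id) |>
    dplyr::group_map(function(df, key) {
      sc <- score_organism(df)
      stats::setNames(sc$score, sc$repeat_class)[classes]
    }, .keep = TRUE)
  names(per_org) <- class_stats_all |>
    dplyr::group_by(.data$organism_id) |>
    dplyr::group_keys() |>
    dplyr::pull(.data$organism_id)
  scores <- do.call(rbind, per_org[organism_order])
  dimnames(scores) <- list(organism_order, classes)
  structure(list(scores = scores, organisms = organism_order,
                 classes = classes),
            class = "ssr_score_matrix")
}

#' @export
as.matrix.ssr_score_matrix <- function(x, ...) x$scores

#' @export
print.ssr_score_matrix <- function(x, ...) {
  cat("SSR enrichment score matrix: ", length(x$organisms), " organisms x ",
      length(x$classes), " repeat classes\n", sep = "")
  cat("scores in {-2,-1,0,1,2,3}; ",
      sum(x$scores == 3L), " top-10 cells, ",
      sum(x$scores == -2L), " near-absent (frequency < 10) cells\n", sep = "")
  invisible(x)
}

#' Cluster repeat classes by score profile
#'
#' Hierarchical clustering of the matrix columns using Euclidean distance,
#' as used to order the enrichment heat map. The linkage method affects only
#' display order, never the scores themselves.
#'
#' @param x An `ssr_score_matrix`.
#' @param method Linkage method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return List with `order` (classes in dendrogram order) and `hclust`
#'   (the fitted tree, labels = class motifs).
#' @export
cluster_classes <- function(x, method = "average") {
  stopifnot(inherits(x, "ssr_score_matrix"))
  if (length(x$classes) < 2) stop("need >= 2 classes to cluster",
                                  call. = FALSE)
  d <- stats::dist(t(x$scores), method = "euclidean")
  hc <- stats::hclust(d, method = method)
  list(order = x$classes[hc$order], hclust = hc)
}

#' Test a clade-specific repeat-class signature
#'
#' A class is uniquely abundant (a signature) in a clade when it ranks in the
#' top 10 by density in every clade member and in no organism outside the
#' clade. Significance is assessed by a two-sided Welch t-test of the class's
#' densities, clade versus all other organisms.
#'
#' @param class_stats_all Row-bound [per_class_stats()] tibbles.
#' @param repeat_class Canonical class motif to test.
#' @param clade_ids Organism ids forming the clade; must be a proper nonempty
#'   subset, with at least 2 organisms outside it.
#' @return One-row tibble: `repeat_class`, `clade`, `n_clade`, `n_other`,
#'   `uniquely_abundant`, `mean_density_clade`, `mean_density_other`,
#'   `t_statistic`, `p_value` (`NA` when densities are degenerate).
#' @export
signature_test <- function(class_stats_all, repeat_class, clade_ids) {
  orgs <- unique(class_stats_all$organism_id)
  if (length(clade_ids) == 0 || !all(clade_ids %in% orgs)) {
    stop("clade_ids must be a nonempty subset of the cohort", call. = FALSE)
  }
  others <- setdiff(orgs, clade_ids)
  if (length(others) < 2) {
    stop("clade must be a proper subset with >= 2 organisms outside it",
         call. = FALSE)
  }
  ranks <- class_stats_all |>
    dplyr::group_by(.data$organism_id) |>
    dplyr::mutate(rank = rank_classes(dplyr::pick(dplyr::everything()))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$repeat_class == .env$repeat_class)
  in_clade <- ranks$organism_id %in% clade_ids
  unique_abund <- all(ranks$rank[in_clade] <= 10) &&
    all(ranks$rank[!in_clade] > 10)
  x <- ranks$density[in_clade]
  y <- ranks$density[!in_clade]
  tt <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                 error = function(e) NULL)
  tibble::tibble(
    repeat_class = repeat_class,
    clade = paste(clade_ids, collapse = ","),
    n_clade = length(x),
    n_other = length(y),
    uniquely_abundant = unique_abund,
    mean_density_clade = mean(x),
    mean_density_other = mean(y),
    t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value
  )
}

#' Signature tests for several clades
#'
#' Runs [signature_test()] for every (clade, class) pair and applies a
#' multiple-testing correction across tests.
#'
#' @param class_stats_all Row-bound [per_class_stats()] tibbles.
#' @param clades Named list: clade name -> character vector of organism ids.
#' @param classes Character vector of classes to test per clade; by default
#'   every class that is top-10 in at least one member of the clade.
#' @param p_adjust_method Passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return Tibble of [signature_test()] rows plus `clade_name` and
#'   `p_adjusted`.
#' @export
signature_scan <- function(class_stats_all, clades, classes = NULL,
                           p_adjust_method = "bonferroni") {
  res <- purrr::imap(clades, function(ids, nm) {
    cls <- classes
    if (is.null(cls)) {
      rk <- class_stats_all |>
        dplyr::filter(.data$organism_id %in% ids) |>
        dplyr::group_by(.data$organism_id) |>
        dplyr::mutate(rank = rank_classes(dplyr::pick(dplyr::everything()))) |>
        dplyr::ungroup() |>
        dplyr::filter(.data$rank <= 10)
      cls <- sort(unique(rk$repeat_class))
    }
    purrr::map(cls, function(cl) {
      signature_test(class_stats_all, cl, ids)
    }) |>
      dplyr::bind_rows() |>
      dplyr::mutate(clade_name = nm, .before = 1)
  }) |>
    dplyr::bind_rows()
  res$p_adjusted <- stats::p.adjust(res$p_value, method = p_adjust_method)
  res
}

#' Export / read the heat map score matrix as JSON
#'
#' Writes a key/value document (`organisms`, `classes`, `scores` as a row
#' array) loadable by heat map viewers.
#'
#' @param x An `ssr_score_matrix`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_heatmap_json <- function(x, path) {
  stopifnot(inherits(x, "ssr_score_matrix"))
  obj <- list(organisms = x$organisms, classes = x$classes,
              scores = unname(apply(x$scores, 1, identity, simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_json
#' @return `read_heatmap_json()` returns the reconstructed
#'   `ssr_score_matrix`.
#' @export
read_heatmap_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scores <- matrix(as.integer(t(obj$scores)), nrow = length(obj$organisms),
                   byrow = TRUE,
                   dimnames = list(obj$organisms, obj$classes))
  structure(list(scores = scores, organisms = obj$organisms,
                 classes = obj$classes),
            class = "ssr_score_matrix")
}
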