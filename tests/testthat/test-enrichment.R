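# helper: per-class stats with chosen densities/frequencies, zero elsewhere
stats_with <- function(org, dens, freq = NULL) {
  cls <- enumerate_classes(6)$canonical
  out <- tibble::tibble(organism_id = org, repeat_class = cls,
                        frequency = 0L, bases = 0, density = 0)
  idx <- match(names(dens), cls)
  stopifnot(!anyNA(idx))
  out$density[idx] <- unname(dens)
  out$frequency[idx] <- if (is.null(freq)) 1000L else as.integer(unname(freq))
  out$bases[idx] <- out$density[idx]  # arbitrary consistent filler
  out
}

test_that("scores follow the rank bands and the frequency override", {
  dens <- stats::setNames(seq(5000, 10, length.out = 120),
                          enumerate_classes(6)$canonical[1:120])
  st <- stats_with("o1", dens)
  sc <- score_organism(st)
  by_rank <- sc$score[order(sc$rank)]
  expect_equal(by_rank[1:10], rep(3L, 10))
  expect_equal(by_rank[11:25], rep(2L, 15))
  expect_equal(by_rank[26:100], rep(1L, 75))
  expect_equal(by_rank[101:120], rep(0L, 20))
  # zero-density classes have frequency 0 -> -2 (not -1), even in the
  # bottom-100 rank band
  expect_equal(sort(unique(by_rank[402:501])), -2L)
  # frequency < 10 overrides a top rank
  st2 <- st
  st2$frequency[st2$repeat_class == names(dens)[8]] <- 3L
  sc2 <- score_organism(st2)
  expect_equal(sc2$score[sc2$repeat_class == names(dens)[8]], -2L)
  expect_equal(sc2$rank[sc2$repeat_class == names(dens)[8]], 8L)
})

test_that("bottom-100 band scores -1 only with frequency >= 10", {
  cls <- enumerate_classes(6)$canonical
  dens <- stats::setNames(seq(501, 1), cls)  # every class has density
  st <- stats_with("o1", dens)
  sc <- score_organism(st)
  expect_equal(sum(sc$score == -1L), 100)
  expect_equal(sc$score[sc$rank > 401], rep(-1L, 100))
})

test_that("an organism with exactly 10 well-sampled classes scores 3/-2 only", {
  cls <- enumerate_classes(6)$canonical
  dens <- stats::setNames(c(seq(1000, 100, length.out = 10),
                            seq(90, 50, length.out = 30)),
                          cls[1:40])
  freq <- c(rep(500L, 10), rep(5L, 30))
  st <- stats_with("o1", dens, freq)
  sc <- score_organism(st)
  expect_equal(sum(sc$score == 3L), 10)
  expect_equal(sum(sc$score == -2L), 491)
  expect_length(setdiff(unique(sc$score), c(3L, -2L)), 0)
})

test_that("score matrix invariants hold on random cohorts", {
  stats_all <- simulate_class_stats(n_organisms = 8, seed = 202)
  sm <- build_score_matrix(stats_all)
  expect_true(all(sm$scores %in% c(-2L, -1L, 0L, 1L, 2L, 3L)))
  expect_true(all(rowSums(sm$scores == 3L) <= 10))
  expect_true(all(rowSums(sm$scores >= 2L) <= 25))
  expect_true(all(rowSums(sm$scores >= 1L) <= 100))
  # every cell with underlying frequency < 10 is -2
  joined <- dplyr::left_join(tidy(sm), stats_all,
                             by = c("organism_id", "repeat_class"))
  expect_true(all(joined$score[joined$frequency < 10] == -2L))
  expect_error(build_score_matrix(stats_all, organism_order = c("org01",
                                                                "org01")),
               "duplicate")
})

test_that("scores are scale invariant in density and shift invariant in frequency", {
  stats_all <- simulate_class_stats(n_organisms = 3, seed = 7)
  one <- stats_all[stats_all$organism_id == "org01", ]
  base <- score_organism(one)
  scaled <- dplyr::mutate(one, density = density * 37.5)
  expect_equal(score_organism(scaled)$score, base$score)
  shifted <- dplyr::mutate(one, frequency = ifelse(frequency >= 10,
                                                   frequency + 1000L,
                                                   frequency))
  expect_equal(score_organism(shifted)$score, base$score)
})

test_that("disjoint planted classes give a block pattern of 3s", {
  orgs <- c("x", "y", "z")
  cls <- c("AC", "AAG", "AGAT")
  stats_all <- purrr::map2_dfr(orgs, cls, function(o, cl) {
    stats_with(o, stats::setNames(1000, cl))
  })
  sm <- build_score_matrix(stats_all)
  m <- as.matrix(sm)
  for (i in 1:3) {
    expect_equal(unname(m[orgs[i], cls[i]]), 3L)
    expect_true(all(m[orgs[i], setdiff(cls, cls[i])] == -2L))
  }
})

test_that("heatmap JSON round-trips all entries", {
  stats_all <- simulate_class_stats(n_organisms = 4, seed = 99)
  sm <- build_score_matrix(stats_all)
  path <- withr::local_tempfile(fileext = ".json")
  write_heatmap_json(sm, path)
  back <- read_heatmap_json(path)
  expect_equal(back$organisms, sm$organisms)
  expect_equal(back$classes, sm$classes)
  expect_equal(unname(back$scores), unname(sm$scores))
})

test_that("clustering pairs identical columns and matches the O(n^3) reference", {
  scores <- rbind(c(0, 3, 3, -2, 1, 0, 2, -1),
                  c(0, 3, 3, -2, 1, 1, 2, -1),
                  c(1, 3, 3, -2, 0, 0, 2, -2),
                  c(0, 2, 2, -2, 1, 0, 3, -1),
                  c(0, 3, 3, -1, 1, 0, 2, -1),
                  c(2, 3, 3, -2, 1, 0, 2, -1))
  cls <- paste0("c", 1:8)
  sm <- structure(list(scores = `dimnames<-`(scores, list(paste0("o", 1:6),
                                                          cls)),
                       organisms = paste0("o", 1:6), classes = cls),
                  class = "ssr_score_matrix")
  out <- cluster_classes(sm)
  # identical columns c2/c3 must merge first and sit adjacent
  ord <- out$order
  expect_equal(abs(which(ord == "c2") - which(ord == "c3")), 1)
  ref <- ref_average_linkage(sm$scores)
  expect_equal(out$hclust$height, ref$heights, tolerance = 1e-10)
  for (step in seq_along(ref$partitions)) {
    k <- 8 - step
    if (k < 1) break
    expect_true(same_partition(stats::cutree(out$hclust, k = k),
                               ref$partitions[[step]]))
  }
})

test_that("signature_test applies the top-10 uniqueness rule and Welch test", {
  cls <- "AACAGC"
  orgs <- sprintf("org%02d", 1:9)
  stats_all <- purrr::map_dfr(orgs, function(o) {
    dens <- stats::setNames(seq(900, 100, length.out = 12),
                            enumerate_classes(6)$canonical[10:21])
    extra <- if (o %in% orgs[1:3]) 5000 + (match(o, orgs) - 1) * 150
             else runif(1, 0, 4)
    stats_with(o, c(dens, stats::setNames(extra, cls)))
  })
  res <- signature_test(stats_all, cls, orgs[1:3])
  expect_true(res$uniquely_abundant)
  expect_lt(res$p_value, 0.05)
  # clade covering the whole cohort is rejected
  expect_error(signature_test(stats_all, cls, orgs), "proper subset")
  # identical density everywhere: not uniquely abundant, missing p
  flat <- purrr::map_dfr(orgs, function(o) {
    stats_with(o, stats::setNames(c(100, 50), c("AC", "AAG")))
  })
  res2 <- signature_test(flat, "AC", orgs[1:3])
  expect_false(res2$uniquely_abundant)
  expect_true(is.na(res2$p_value))
})

test_that("tidy/glance/autoplot work on the score matrix", {
  stats_all <- simulate_class_stats(n_organisms = 3, seed = 15)
  sm <- build_score_matrix(stats_all)
  td <- tidy(sm)
  expect_equal(nrow(td), 3 * 501)
  expect_equal(sum(td$score == 3L), unname(glance(sm)$n_top10))
  p <- ggplot2::autoplot(sm)
  expect_s3_class(p, "ggplot")
})
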