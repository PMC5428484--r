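test_that("ortholog reader filters high-identity pairs and enforces one-to-one", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(idA = c("a1", "a2", "a3"), idB = c("b1", "b2", "b3"),
                   pct_identity = c(50, 85, 79.9))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  orth <- suppressMessages(read_orthologs(path))
  expect_equal(orth$idA, c("a1", "a3"))
  expect_true(all(orth$pct_identity < 80))

  bad <- data.frame(idA = c("a1", "a1"), idB = c("b1", "b2"))
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_orthologs(path), "one-to-one")
})

test_that("controls are derangements: bijective and fixed-point-free", {
  cases <- data.frame(idA = sprintf("a%d", 1:2), idB = sprintf("b%d", 1:2))
  ctrl <- make_controls(cases, seed = 1)
  expect_equal(ctrl$idB, c("b2", "b1"))  # the unique derangement of size 2

  cases3 <- data.frame(idA = sprintf("a%d", 1:3), idB = sprintf("b%d", 1:3))
  ctrl3 <- make_controls(cases3, seed = 5)
  expect_true(all(ctrl3$idB != cases3$idB))
  expect_setequal(ctrl3$idB, cases3$idB)

  cases20 <- data.frame(idA = sprintf("a%d", 1:20),
                        idB = sprintf("b%d", 1:20))
  for (s in 1:25) {
    c20 <- make_controls(cases20, seed = s)
    expect_setequal(c20$idB, cases20$idB)       # bijection
    expect_true(all(c20$idB != cases20$idB))    # no fixed points
  }
  expect_error(make_controls(cases20[1, ]), "derangement")
})

test_that("every non-identity position is reachable across repeats", {
  cases <- data.frame(idA = sprintf("a%d", 1:5), idB = sprintf("b%d", 1:5))
  set.seed(8)
  hits <- matrix(0, 5, 5)
  for (r in 1:300) {
    ctrl <- make_controls(cases)
    hits[cbind(seq_len(5), match(ctrl$idB, cases$idB))] <-
      hits[cbind(seq_len(5), match(ctrl$idB, cases$idB))] + 1
  }
  expect_true(all(diag(hits) == 0))
  off <- hits[row(hits) != col(hits)]
  expect_true(all(off > 0))
})

test_that("optimal threshold handles separable, mixed and degenerate inputs", {
  sep <- optimal_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(sep$error_rate, 0)
  expect_equal(sep$h_star, 0.5)  # midpoint of the separating gap
  expect_equal(c(sep$tp, sep$fp, sep$tn, sep$fn), c(2, 0, 2, 0))

  mixed <- optimal_threshold(c(0.6, 0.2), c(0.5, 0.1))
  expect_equal(mixed$error_rate, 0.25)

  same <- optimal_threshold(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(same$error_rate, 0.5)
})

test_that("optimal threshold equals a brute-force scan over every cut", {
  set.seed(13)
  for (i in 1:30) {
    cases <- round(runif(8), 2)
    controls <- round(runif(8), 2)
    got <- optimal_threshold(cases, controls)
    # brute force: try every observed score under both >= and > rules
    cand <- c(-Inf, sort(unique(c(cases, controls))), Inf)
    errs_ge <- vapply(cand, function(h)
      (sum(controls >= h) + sum(cases < h)) / 16, numeric(1))
    errs_gt <- vapply(cand, function(h)
      (sum(controls > h) + sum(cases <= h)) / 16, numeric(1))
    expect_equal(got$error_rate, min(c(errs_ge, errs_gt)))
    # no candidate beats the reported threshold
    expect_true(all(errs_ge >= got$error_rate - 1e-12))
    expect_lte(got$error_rate, 0.5)
  }
})

test_that("swapping class labels mirrors the threshold direction", {
  set.seed(19)
  cases <- runif(20, 0.5, 1); controls <- runif(20, 0, 0.5)
  a <- optimal_threshold(cases, controls)
  b <- optimal_threshold(-controls, -cases)  # label swap == axis flip
  expect_equal(a$error_rate, b$error_rate)
})

test_that("perfect and constant scorers bracket the benchmark", {
  cases <- data.frame(idA = sprintf("a%d", 1:30),
                      idB = sprintf("b%d", 1:30))
  perfect <- function(a, b) as.numeric(sub("a", "", a) == sub("b", "", b))
  bp <- repeat_benchmark(cases, perfect, R = 10, seed = 2)
  expect_equal(bp$raw$mean_error, 0)
  expect_equal(unname(bp$raw$ci), c(0, 0))

  constant <- function(a, b) 0.5
  bc <- repeat_benchmark(cases, constant, R = 10, seed = 2)
  expect_true(all(bc$raw$errors == 0.5))
})

test_that("confidence interval brackets the mean and summary is tidy", {
  cases <- data.frame(idA = sprintf("a%d", 1:40),
                      idB = sprintf("b%d", 1:40))
  noisy <- function(a, b) {
    if (sub("a", "", a) == sub("b", "", b)) rnorm(1, 0.6, 0.1)
    else rnorm(1, 0.4, 0.1)
  }
  bench <- repeat_benchmark(cases, noisy, R = 40, seed = 3)
  expect_lte(bench$raw$ci["lo"], bench$raw$mean_error)
  expect_gte(bench$raw$ci["hi"], bench$raw$mean_error)
  s <- summary(bench)
  expect_equal(s$scores, "raw")
  expect_equal(s$mean_error, bench$raw$mean_error)
})

test_that("unscorable case pairs are excluded before control construction", {
  cases <- data.frame(idA = sprintf("a%d", 1:12),
                      idB = sprintf("b%d", 1:12))
  scorer <- function(a, b) {
    if (a == "a1") return(NA_real_)
    as.numeric(sub("a", "", a) == sub("b", "", b))
  }
  bench <- suppressMessages(repeat_benchmark(cases, scorer, R = 5, seed = 4))
  expect_equal(bench$n_pairs, 11)
  expect_equal(bench$n_excluded, 1)
  expect_equal(bench$raw$mean_error, 0)
})

test_that("the z-score arm runs alongside the raw arm", {
  ctx <- tiny_ctx()
  w <- tiny_world()
  orth <- suppressMessages(read_orthologs(w$paths$orthologs))
  scorer <- fs_scorer(ctx$corpus, ctx$dags, ctx$ics, "simLin", "fsBMA",
                      "BP")
  prot <- unique(c(orth$idA, orth$idB))
  poolB <- grep("^B", names(ctx$corpus$direct$BP), value = TRUE)
  poolA <- grep("^A", names(ctx$corpus$direct$BP), value = TRUE)
  bg <- rbind(
    estimate_background(grep("^A", prot, value = TRUE), poolB, scorer,
                        k = 15, seed = 5),
    estimate_background(grep("^B", prot, value = TRUE), poolA, scorer,
                        k = 15, seed = 6))
  bench <- repeat_benchmark(orth, scorer, R = 15, seed = 7,
                            background = bg)
  expect_false(is.null(bench$z))
  expect_length(bench$z$errors, 15)
  expect_lte(bench$z$mean_error, 0.5)
  s <- summary(bench)
  expect_setequal(s$scores, c("raw", "z"))
})

test_that("corpus comparison: dominance, degeneracy and direction", {
  set.seed(23)
  e_all <- runif(225, 0.05, 0.15)
  res <- compare_corpora(e_all, e_all + 0.01)
  expect_lt(res$p_value, 1e-10)
  expect_true(res$significant)

  same <- compare_corpora(e_all, e_all)
  expect_true(same$degenerate)
  expect_false(same$significant)

  # AOO better than ALL should not reject under the default direction
  res2 <- compare_corpora(e_all, e_all - 0.01)
  expect_false(res2$significant)
})

test_that("corpus comparison holds its nominal level under the null", {
  set.seed(29)
  n_sim <- 400
  rejections <- 0
  for (i in seq_len(n_sim)) {
    base <- runif(40, 0.1, 0.2)
    a <- base + rnorm(40, 0, 0.01)
    b <- base + rnorm(40, 0, 0.01)
    res <- compare_corpora(a, b, n_tests = 1, alpha = 0.05)
    rejections <- rejections + res$significant
  }
  rate <- rejections / n_sim
  # one-sided alpha = 0.05: Monte-Carlo band of +-3 binomial SDs
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim) + 1e-9)
})
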