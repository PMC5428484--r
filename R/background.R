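#' Per-protein background distribution of a functional-similarity score
#'
#' For each query protein, samples `k` partner proteins without
#' replacement from the partner organism's annotated pool, scores every
#' (query, partner) pair, and records the mean and (sample) standard
#' deviation. These backgrounds feed the similarity z-score, which
#' corrects for annotation bias: heavily or shallowly annotated proteins
#' carry systematically shifted raw scores, and their own background
#' calibrates what "high" means for them.
#'
#' Unscorable pairs (`score_fun` returns `NA`) are skipped and
#' `n_sampled` reduced accordingly, so backgrounds are estimated over
#' annotated partners only. With a fixed `seed` the estimate is
#' bit-reproducible.
#'
#' @param proteins character vector of query protein ids.
#' @param pool character vector of candidate partner ids, restricted to
#'   proteins annotated in the scoring namespaces.
#' @param score_fun `function(idA, idB)` returning a numeric score or
#'   `NA`; typically [fs_scorer()].
#' @param k partners sampled per protein (default 1000); clamped to the
#'   pool size with a warning when larger.
#' @param seed optional integer seed.
#' @return an `fs_background` data.frame with columns `protein`, `mu`,
#'   `sigma`, `n_sampled`.
#' @export
estimate_background <- function(proteins, pool, score_fun, k = 1000,
                                seed = NULL) {
  if (length(pool) == 0) stop_gofunsim("partner pool is empty")
  if (k > length(pool)) {
    warning(sprintf("k = %d exceeds pool size %d; clamping", k, length(pool)))
    k <- length(pool)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(proteins, function(p) {
    partners <- if (k == length(pool)) pool else sample(pool, k)
    sc <- vapply(partners, function(q) score_fun(p, q), numeric(1))
    sc <- sc[!is.na(sc)]
    data.frame(protein = p,
               mu = if (length(sc)) mean(sc) else NA_real_,
               sigma = if (length(sc) > 1) stats::sd(sc) else NA_real_,
               n_sampled = length(sc))
  })
  out <- do.call(rbind, rows)
  attr(out, "context") <- list(k = k, seed = seed, pool_size = length(pool))
  class(out) <- c("fs_background", "data.frame")
  out
}

#' Similarity z-score
#'
#' Normalizes a raw functional-similarity score F(P, R) against the two
#' proteins' background distributions:
#'
#'   z = (2 F - (mu_P + mu_R)) / sqrt(sigma_P^2 + sigma_R^2)
#'
#' motivated by the central limit theorem for the sum of the two
#' per-protein scores. z is strictly increasing in F for fixed
#' backgrounds and vanishes when F equals the average of the two
#' background means. When both sigmas are zero the z-score is undefined
#' and `NA` is returned with a warning (the raw score remains usable).
#'
#' @param f raw score(s) F(P, R); vectorized.
#' @param mu_p,sigma_p background mean and SD of protein P.
#' @param mu_r,sigma_r background mean and SD of protein R.
#' @return numeric vector of z-scores.
#' @export
zscore <- function(f, mu_p, sigma_p, mu_r, sigma_r) {
  denom <- sqrt(sigma_p^2 + sigma_r^2)
  bad <- !is.na(denom) & denom == 0
  if (any(bad))
    warning(sprintf("%d pair(s) with zero background variance: z undefined, returning NA",
                    sum(bad)))
  out <- (2 * f - (mu_p + mu_r)) / denom
  out[bad] <- NA_real_
  out
}

# z-scores for pairs via a background table; NA for proteins without stats
zscore_pairs <- function(f, idA, idB, background) {
  i <- match(idA, background$protein)
  j <- match(idB, background$protein)
  suppressWarnings(
    zscore(f, background$mu[i], background$sigma[i],
           background$mu[j], background$sigma[j]))
}

#' Persist / reload background tables
#'
#' Backgrounds are the expensive precomputation of the pipeline (pool
#' size times k scorings); the TSV round-trip lets them be computed once
#' and reused across runs. Context (k, seed, pool size) is stored in a
#' comment header.
#'
#' @param bg an `fs_background`.
#' @param path TSV path.
#' @return `path` (write) or an `fs_background` (read).
#' @export
write_background <- function(bg, path) {
  ctx <- attr(bg, "context")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%s seed=%s pool_size=%s",
                     ctx$k %||% NA, ctx$seed %||% NA, ctx$pool_size %||% NA),
             con)
  utils::write.table(bg, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  out <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  class(out) <- c("fs_background", "data.frame")
  out
}
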