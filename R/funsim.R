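MIX_STRATEGIES <- c("fsAvg", "fsMax", "fsBMM", "fsBMA", "fsABM")

#' Semantic-similarity matrix of a protein pair
#'
#' Builds the m-by-n matrix of pairwise term similarities over the two
#' proteins' direct annotation sets in one namespace (rows: terms of
#' `idA`; columns: terms of `idB`; both deduplicated and sorted, so the
#' matrix is deterministic). Only direct annotations populate the matrix;
#' the ancestor closure enters through the information content and
#' through simGIC's ancestor sums.
#'
#' @param idA,idB protein identifiers as they appear in GAF column 2.
#' @param corpus a `go_corpus` under the active filter.
#' @param dag,ic the namespace's `go_dag` and `go_ic`.
#' @param measure semantic-similarity measure, see [term_sim()].
#' @param ... passed to [term_sim_matrix()].
#' @return an `ss_matrix`: numeric matrix with term-id dimnames and
#'   attributes `measure`, `namespace`, `proteins`.
#' @export
ss_matrix <- function(idA, idB, corpus, dag, ic, measure, ...) {
  ns <- dag$namespace
  ta <- corpus$direct[[ns]][[idA]]
  tb <- corpus$direct[[ns]][[idB]]
  if (is.null(ta) || length(ta) == 0)
    stop_unscorable("protein '%s' has no %s annotation under the active filter",
                    idA, ns)
  if (is.null(tb) || length(tb) == 0)
    stop_unscorable("protein '%s' has no %s annotation under the active filter",
                    idB, ns)
  M <- term_sim_matrix(dag, ic, sort(ta), sort(tb), measure, ...)
  structure(M, measure = measure, namespace = ns, proteins = c(idA, idB),
            class = c("ss_matrix", class(M)))
}

#' Mixing strategies: matrix to functional-similarity score
#'
#' Aggregates an m-by-n term-similarity matrix into one functional
#' similarity value. With rowmax_i the maximum of row i and colmax_j the
#' maximum of column j:
#'
#' * `fsAvg` — mean over all cells
#' * `fsMax` — maximum cell
#' * `fsBMM` — max( mean(rowmax), mean(colmax) )
#' * `fsBMA` — ( mean(rowmax) + mean(colmax) ) / 2
#' * `fsABM` — ( sum(rowmax) + sum(colmax) ) / (m + n)
#'
#' All five are transpose-symmetric and coincide on a 1-by-1 matrix, and
#' satisfy fsAvg <= fsABM, fsBMA <= fsBMM <= fsMax.
#'
#' @param M numeric matrix (an `ss_matrix` or any matrix with at least one
#'   row and column).
#' @param mix character vector of strategies to evaluate; all five by
#'   default.
#' @return named numeric vector of the requested strategies.
#' @examples
#' M <- matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)
#' mix_score(M)                 # all five strategies
#' mix_score(M, "fsBMA")
#' @export
mix_score <- function(M, mix = MIX_STRATEGIES) {
  M <- unclass(M)
  stopifnot(is.matrix(M), nrow(M) >= 1, ncol(M) >= 1, !anyNA(M))
  mix <- match.arg(mix, MIX_STRATEGIES, several.ok = TRUE)
  rowmax <- apply(M, 1, max)
  colmax <- apply(M, 2, max)
  m <- nrow(M); n <- ncol(M)
  vals <- c(fsAvg = mean(M),
            fsMax = max(M),
            fsBMM = max(mean(rowmax), mean(colmax)),
            fsBMA = (mean(rowmax) + mean(colmax)) / 2,
            fsABM = (sum(rowmax) + sum(colmax)) / (m + n))
  vals[mix]
}

#' Combine per-ontology scores
#'
#' Root-mean-square combination of functional-similarity scores across
#' ontologies, e.g. F_BP+MF = sqrt((F_BP^2 + F_MF^2)/2). Any subset of
#' namespaces may be combined. Every requested namespace must have a
#' score: a protein pair missing one namespace is unscorable for the
#' combination, whereas a present zero enters the RMS (and drags it
#' down).
#'
#' @param scores named numeric vector of per-namespace scores.
#' @param which namespaces to combine; defaults to all of `scores`.
#' @return the combined score (numeric scalar).
#' @export
combine_fs <- function(scores, which = names(scores)) {
  if (!all(which %in% names(scores)) || anyNA(scores[which]))
    stop_unscorable("missing namespace score(s): %s",
                    paste(setdiff(which, names(scores)[!is.na(scores)]),
                          collapse = ", "))
  sqrt(mean(scores[which]^2))
}

#' Functional similarity of a protein pair
#'
#' End-to-end score: builds the term-similarity matrix per requested
#' namespace, applies the mixing strategy, and combines namespaces by
#' root mean square when more than one is requested. If either protein
#' lacks annotation in any requested namespace the pair is unscorable and
#' a classed error (`gofunsim_unscorable`) is raised — distinct from a
#' score of zero.
#'
#' @inheritParams ss_matrix
#' @param dags,ics named lists of `go_dag` / `go_ic` covering
#'   `namespaces`.
#' @param mix one mixing strategy, see [mix_score()].
#' @param namespaces character vector, subset of `c("BP","MF","CC")`.
#' @return an `fs_score`: list with `value`, `per_namespace` (data.frame
#'   of namespace, score, m, n), `measure`, `mix`, `namespaces`.
#' @export
fun_sim <- function(idA, idB, corpus, dags, ics, measure, mix,
                    namespaces = "BP", ...) {
  mix <- match.arg(mix, MIX_STRATEGIES)
  per <- lapply(namespaces, function(ns) {
    M <- ss_matrix(idA, idB, corpus, dags[[ns]], ics[[ns]], measure, ...)
    data.frame(namespace = ns,
               score = unname(mix_score(M, mix)),
               m = nrow(M), n = ncol(M))
  })
  per <- do.call(rbind, per)
  scores <- stats::setNames(per$score, per$namespace)
  value <- if (length(namespaces) > 1) combine_fs(scores, namespaces)
           else unname(scores[[namespaces]])
  structure(list(value = value, per_namespace = per, measure = measure,
                 mix = mix, namespaces = namespaces,
                 proteins = c(idA, idB)),
            class = "fs_score")
}

#' @export
print.fs_score <- function(x, ...) {
  cat(sprintf("%s/%s %s(%s, %s) = %.9g\n", x$measure, x$mix,
              paste(x$namespaces, collapse = "+"),
              x$proteins[1], x$proteins[2], x$value))
  if (length(x$namespaces) > 1)
    print(x$per_namespace, row.names = FALSE)
  invisible(x)
}

#' Scorer closure for backgrounds and benchmarks
#'
#' Wraps [fun_sim()] into a `function(idA, idB)` returning the raw score,
#' or `NA` when the pair is unscorable under the requested namespaces —
#' the calling convention expected by [estimate_background()] and
#' [repeat_benchmark()].
#'
#' @inheritParams fun_sim
#' @return a function of two protein ids returning numeric or `NA`.
#' @export
fs_scorer <- function(corpus, dags, ics, measure, mix, namespaces = "BP",
                      ...) {
  force(corpus); force(dags); force(ics)
  function(idA, idB) {
    tryCatch(fun_sim(idA, idB, corpus, dags, ics, measure, mix,
                     namespaces, ...)$value,
             gofunsim_unscorable = function(e) NA_real_)
  }
}

#' Dump a semantic-similarity matrix as TSV
#'
#' Long-format export of an [ss_matrix()]: one line per cell with flags
#' marking row maxima, column maxima, or both — the cells that the
#' best-match mixing strategies aggregate.
#'
#' @param M an `ss_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ss_matrix <- function(M, path) {
  rowmax <- apply(M, 1, max)
  colmax <- apply(M, 2, max)
  df <- expand.grid(row_term = rownames(M), col_term = colnames(M),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$score <- format_score(M[cbind(df$row_term, df$col_term)])
  df$is_row_max <- M[cbind(df$row_term, df$col_term)] == rowmax[df$row_term]
  df$is_col_max <- M[cbind(df$row_term, df$col_term)] == colmax[df$col_term]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
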