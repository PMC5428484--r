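#' Information-content table for one namespace
#'
#' For every term t, counts the number of distinct proteins annotated to t
#' or to any of its descendants (a protein annotated to two descendants of
#' t counts once), converts counts to probabilities P(t) = N(t)/N(root),
#' and derives the information content I(t) = -log P(t). The root has
#' P = 1 and I = 0 by construction. Terms with no annotated protein are
#' unscorable: they carry P = 0 and I = NA, and similarity computations
#' treat them as contributing nothing.
#'
#' Counting is implemented by propagating each protein's direct terms up
#' the ancestor closure and counting each ancestor once per protein, which
#' is equivalent to (and much cheaper than) enumerating descendants per
#' term.
#'
#' @param corpus a `go_corpus`; probabilities are always relative to this
#'   corpus under its active filter.
#' @param dag the `go_dag` of the namespace to tabulate.
#' @param base logarithm base for I(t). Natural log by default (the
#'   classic Resnik convention); the base only rescales the Resnik
#'   measure, every normalized measure is base-invariant.
#' @return a `go_ic`: list with `namespace`, `N`, `P`, `I` (named numeric
#'   vectors over all terms), `n_root`, and `base`.
#' @export
build_ic <- function(corpus, dag, base = exp(1)) {
  stopifnot(inherits(corpus, "go_corpus"), inherits(dag, "go_dag"))
  ns <- dag$namespace
  direct <- corpus$direct[[ns]]
  direct <- lapply(direct, function(ts) ts[ts %in% dag$ids])
  direct <- Filter(length, direct)
  if (length(direct) == 0)
    stop_gofunsim("no annotated proteins in namespace %s", ns)

  anc <- ancestor_table(dag)
  N <- stats::setNames(integer(length(dag$ids)), dag$ids)
  for (p in names(direct)) {
    a <- unique(unlist(anc[direct[[p]]], use.names = FALSE))
    N[a] <- N[a] + 1L
  }
  n_root <- unname(N[dag$root])
  P <- N / n_root
  I <- -log(P) / log(base)
  I[N == 0L] <- NA_real_
  structure(list(namespace = ns, N = N, P = P, I = I,
                 n_root = n_root, base = base),
            class = "go_ic")
}

#' @export
print.go_ic <- function(x, ...) {
  cat(sprintf("Information content [%s]: %d terms, %d annotated proteins, %d unscorable term(s), max I = %.4f\n",
              x$namespace, length(x$N), x$n_root, sum(x$N == 0),
              max(x$I, na.rm = TRUE)))
  invisible(x)
}

#' Export an information-content table as TSV
#'
#' @param ic a `go_ic` from [build_ic()].
#' @param path output path; columns term, N, P, I (I empty for
#'   unscorable terms).
#' @return `path`, invisibly.
#' @export
write_ic <- function(ic, path) {
  df <- data.frame(term = names(ic$N), N = unname(ic$N),
                   P = unname(ic$P), I = unname(ic$I))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
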