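#' Parse a GAF 2.x annotation corpus
#'
#' Reads a Gene Association File and returns an annotation corpus linking
#' gene products to GO terms with evidence codes and taxa. `NOT`-qualified
#' lines are excluded (they state what a product does *not* do), secondary
#' term accessions are resolved through the ontology's `alt_id` map, and
#' annotations to terms absent from the supplied DAGs are dropped with a
#' logged count. Protein identifiers are taken verbatim from column 2.
#'
#' @param path path to a GAF 2.0/2.1/2.2 file.
#' @param dags named list of `go_dag` objects from [parse_obo()].
#' @return a `go_corpus`: list with `records` (data.frame of protein, term,
#'   evidence, taxon, namespace), `direct` (per-namespace deduplicated
#'   protein -> term sets), `filter_state`, and `n_dropped`.
#' @export
parse_gaf <- function(path, dags) {
  raw <- readLines(path)
  keep <- !grepl("^!", raw) & nzchar(raw)
  line_no <- which(keep)
  if (!any(keep)) {
    return(new_go_corpus(empty_gaf_records(), dags))
  }
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 15 | nf > 17)
  if (length(bad))
    stop_gofunsim("GAF format error at line %d: expected 15-17 columns, found %d",
                  line_no[bad[1]], nf[bad[1]])

  col <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else "",
                            character(1))
  qualifier <- col(4)
  not_q <- grepl("(^|\\|)NOT($|\\|)", qualifier)

  taxon_raw <- col(13)
  taxon <- suppressWarnings(
    as.integer(sub("^taxon:([0-9]+).*$", "\\1", taxon_raw)))

  rec <- data.frame(protein = col(2),
                    term = col(5),
                    evidence = col(7),
                    taxon = taxon,
                    stringsAsFactors = FALSE)
  rec <- rec[!not_q, , drop = FALSE]

  # resolve alt_ids, then map each term to its namespace
  term2ns <- do.call(c, unname(lapply(dags, function(d)
    stats::setNames(rep(d$namespace, length(d$ids)), d$ids))))
  alt_map <- do.call(c, unname(lapply(dags, function(d) d$alt_ids)))
  is_alt <- rec$term %in% names(alt_map)
  rec$term[is_alt] <- unname(alt_map[rec$term[is_alt]])
  rec$namespace <- unname(term2ns[rec$term])

  n_unknown <- sum(is.na(rec$namespace))
  if (n_unknown > 0)
    log_msg("parse_gaf: dropped %d annotation(s) to terms absent from the ontology",
            n_unknown)
  rec <- rec[!is.na(rec$namespace), , drop = FALSE]
  rownames(rec) <- NULL
  new_go_corpus(rec, dags, n_dropped = n_unknown)
}

empty_gaf_records <- function() {
  data.frame(protein = character(0), term = character(0),
             evidence = character(0), taxon = integer(0),
             namespace = character(0), stringsAsFactors = FALSE)
}

new_go_corpus <- function(records, dags = NULL, n_dropped = 0L,
                          filter_state = list(iea = "included", taxa = "ALL")) {
  direct <- lapply(stats::setNames(NAMESPACES, NAMESPACES), function(ns) {
    r <- records[records$namespace == ns, , drop = FALSE]
    if (nrow(r) == 0) return(list())
    lapply(split(r$term, r$protein), function(ts) sort(unique(ts)))
  })
  structure(list(records = records, direct = direct,
                 filter_state = filter_state, n_dropped = n_dropped),
            class = "go_corpus")
}

#' Filter an annotation corpus by evidence and taxon
#'
#' Implements the two corpus axes studied here: inclusion/exclusion of
#' electronically inferred annotations (evidence code IEA), and restriction
#' to the annotations of the organisms under comparison (the AOO corpus)
#' versus all organisms (ALL). Returns a new corpus; information content
#' must be rebuilt from the filtered corpus so that term probabilities are
#' always relative to their own corpus.
#'
#' @param corpus a `go_corpus` from [parse_gaf()].
#' @param iea `"included"` or `"excluded"`.
#' @param taxa `"ALL"` or a vector of NCBI taxon ids to retain.
#' @return a new `go_corpus` with updated `filter_state`.
#' @export
filter_corpus <- function(corpus, iea = c("included", "excluded"),
                          taxa = "ALL") {
  stopifnot(inherits(corpus, "go_corpus"))
  iea <- match.arg(iea)
  rec <- corpus$records
  if (iea == "excluded") rec <- rec[rec$evidence != "IEA", , drop = FALSE]
  if (!identical(taxa, "ALL")) rec <- rec[rec$taxon %in% taxa, , drop = FALSE]
  if (nrow(rec) == 0)
    warning("filter_corpus: filtering produced an empty corpus")
  rownames(rec) <- NULL
  new_go_corpus(rec, n_dropped = corpus$n_dropped,
                filter_state = list(iea = iea, taxa = taxa))
}

#' @export
print.go_corpus <- function(x, ...) {
  np <- length(unique(x$records$protein))
  cat(sprintf("GO annotation corpus: %d records, %d proteins (IEA %s, taxa %s)\n",
              nrow(x$records), np, x$filter_state$iea,
              if (identical(x$filter_state$taxa, "ALL")) "ALL"
              else paste(x$filter_state$taxa, collapse = ",")))
  for (ns in NAMESPACES)
    cat(sprintf("  %s: %d annotated proteins\n", ns, length(x$direct[[ns]])))
  invisible(x)
}

# proteins annotated in every requested namespace, optionally one taxon
annotated_proteins <- function(corpus, namespaces, taxon = NULL) {
  sets <- lapply(namespaces, function(ns) names(corpus$direct[[ns]]))
  ids <- Reduce(intersect, sets)
  if (!is.null(taxon)) {
    in_tax <- unique(corpus$records$protein[corpus$records$taxon %in% taxon])
    ids <- intersect(ids, in_tax)
  }
  sort(ids)
}
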