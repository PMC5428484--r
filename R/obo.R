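#' Parse an OBO ontology into per-namespace DAGs
#'
#' Reads an OBO 1.2/1.4 flat file and returns one directed acyclic graph per
#' GO namespace (biological process, molecular function, cellular component).
#' Obsolete terms are dropped, `alt_id` entries are recorded so annotation
#' readers can resolve secondary accessions, and only edges of the requested
#' relation types are retained. Edges crossing namespaces are discarded, so
#' each DAG is self-contained and scored independently.
#'
#' @param path path to an OBO file.
#' @param relations character vector of relation names defining ancestry.
#'   The default `is_a` + `part_of` is the GO Consortium convention.
#' @return a named list of `go_dag` objects keyed by namespace
#'   (`"BP"`, `"MF"`, `"CC"`; namespaces with no terms are absent).
#' @examples
#' spec <- fixture_spec(n_terms = c(BP = 8, MF = 5, CC = 4),
#'                      n_proteins = c(6, 6), n_orthologs = 3, seed = 1)
#' world <- make_world(spec, dir = tempfile("world"))
#' dags <- parse_obo(world$paths$obo)
#' dags$BP
#' @seealso [go_ancestors()], [parse_gaf()]
#' @export
parse_obo <- function(path, relations = c("is_a", "part_of")) {
  lines <- readLines(path)
  n <- length(lines)

  terms <- list()
  cur <- NULL
  cur_start <- NA_integer_
  in_term <- FALSE

  flush <- function(cur, cur_start) {
    if (is.null(cur)) return(invisible(NULL))
    if (is.null(cur$id))
      stop_gofunsim("OBO parse error: [Term] stanza starting at line %d has no id",
                    cur_start)
    if (!grepl("^GO:[0-9]{7}$", cur$id))
      stop_gofunsim("OBO parse error: malformed term id '%s' (stanza at line %d)",
                    cur$id, cur_start)
    terms[[cur$id]] <<- cur
    invisible(NULL)
  }

  for (i in seq_len(n)) {
    ln <- lines[i]
    if (grepl("^\\s*$", ln) || grepl("^!", ln)) next
    if (grepl("^\\[", ln)) {
      flush(cur, cur_start)
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                    parents = data.frame(parent = character(0),
                                         relation = character(0)),
                    alt_ids = character(0), obsolete = FALSE)
        cur_start <- i
      }
      next
    }
    if (!in_term) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop_gofunsim("OBO parse error at line %d: '%s'", i, ln)
    key <- m[2]; val <- sub("\\s*!.*$", "", m[3])
    val <- trimws(val)
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "alt_id") cur$alt_ids <- c(cur$alt_ids, val)
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "is_a")
      cur$parents <- rbind(cur$parents,
                           data.frame(parent = val, relation = "is_a"))
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2)
        stop_gofunsim("OBO parse error at line %d: bad relationship '%s'", i, val)
      cur$parents <- rbind(cur$parents,
                           data.frame(parent = parts[2], relation = parts[1]))
    }
    # other tags (def, synonym, xref, ...) are ignored
  }
  flush(cur, cur_start)

  live <- Filter(function(t) !t$obsolete, terms)
  if (length(live) == 0)
    stop_gofunsim("OBO file '%s' contains no non-obsolete [Term] stanzas", path)

  ns_raw <- vapply(live, function(t) t$namespace, character(1))
  unknown_ns <- setdiff(unique(ns_raw), names(OBO_NS_MAP))
  if (length(unknown_ns))
    stop_gofunsim("OBO parse error: unknown namespace(s) %s",
                  paste(unknown_ns, collapse = ", "))
  ns <- unname(OBO_NS_MAP[ns_raw])

  out <- list()
  for (space in intersect(NAMESPACES, unique(ns))) {
    ids <- names(live)[ns == space]
    sub <- live[ids]
    edges <- do.call(rbind, lapply(ids, function(id) {
      p <- sub[[id]]$parents
      if (nrow(p) == 0) return(NULL)
      keep <- p$relation %in% relations & p$parent %in% ids
      if (!any(keep)) return(NULL)
      data.frame(child = id, parent = p$parent[keep],
                 relation = p$relation[keep])
    }))
    if (is.null(edges))
      edges <- data.frame(child = character(0), parent = character(0),
                          relation = character(0))
    nm <- vapply(sub, function(t) t$name, character(1))
    alt <- unlist(lapply(ids, function(id) {
      a <- sub[[id]]$alt_ids
      stats::setNames(rep(id, length(a)), a)
    }))
    out[[space]] <- new_go_dag(space, sort(ids), nm[sort(ids)], edges,
                               alt_ids = alt %||% character(0),
                               relations = relations)
  }
  out
}

# construct + validate a single-namespace DAG
new_go_dag <- function(namespace, ids, names, edges, alt_ids = character(0),
                       relations = c("is_a", "part_of")) {
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  parents <- lapply(parents, unique)
  has_parent <- lengths(parents) > 0
  roots <- ids[!has_parent]
  if (length(roots) != 1)
    stop_gofunsim("ontology integrity error: namespace %s has %d parentless terms (%s); expected exactly one root",
                  namespace, length(roots),
                  paste(utils::head(roots, 5), collapse = ", "))

  dag <- structure(list(namespace = namespace,
                        ids = ids,
                        names = names,
                        edges = edges,
                        parents = parents,
                        root = roots,
                        alt_ids = alt_ids,
                        relations = relations,
                        cache = new.env(parent = emptyenv())),
                   class = "go_dag")
  # acyclicity: topological sort must consume every term
  if (length(topo_order(dag)) != length(ids))
    stop_gofunsim("ontology integrity error: namespace %s contains a cycle",
                  namespace)
  dag
}

# parents-before-children order (Kahn's algorithm on child->parent edges)
topo_order <- function(dag) {
  ids <- dag$ids
  idx <- stats::setNames(seq_along(ids), ids)
  npar <- lengths(dag$parents)[ids]
  children <- split(dag$edges$child, factor(dag$edges$parent, levels = ids))
  queue <- ids[npar == 0]
  order <- character(0)
  remaining <- npar
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      remaining[idx[ch]] <- remaining[idx[ch]] - 1L
      if (remaining[idx[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  order
}

# full reflexive-transitive ancestor table, memoised on the dag
ancestor_table <- function(dag) {
  if (!is.null(dag$cache$anc)) return(dag$cache$anc)
  anc <- vector("list", length(dag$ids))
  names(anc) <- dag$ids
  for (id in topo_order(dag)) {
    ps <- dag$parents[[id]]
    anc[[id]] <- sort(unique(c(id, unlist(anc[ps], use.names = FALSE))))
  }
  dag$cache$anc <- anc
  anc
}

#' Ancestor set of a GO term
#'
#' Reflexive-transitive closure over the DAG's retained relations: a term is
#' its own ancestor, and the namespace root belongs to every ancestor set.
#' Reflexivity is what makes self-similarity behave (the most informative
#' common ancestor of a term with itself is the term, and the graph
#' information content measure of a term with itself is 1).
#'
#' @param dag a `go_dag` from [parse_obo()].
#' @param term a term id (primary accession) in `dag`.
#' @return sorted character vector of ancestor term ids, including `term`.
#' @export
go_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "go_dag"))
  anc <- ancestor_table(dag)
  if (is.null(anc[[term]]))
    stop_gofunsim("unknown term id '%s' in namespace %s", term, dag$namespace)
  anc[[term]]
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG [%s]: %d terms, %d edges (%s), root %s (%s)\n",
              x$namespace, length(x$ids), nrow(x$edges),
              paste(x$relations, collapse = "+"),
              x$root, x$names[[x$root]]))
  invisible(x)
}

#' Serialize DAGs back to OBO
#'
#' Writes a minimal OBO 1.2 file (id, name, namespace, alt_id, is_a,
#' relationship) that [parse_obo()] reads back into identical DAGs.
#'
#' @param dags named list of `go_dag` objects, as returned by [parse_obo()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dags, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  rev_ns <- stats::setNames(names(OBO_NS_MAP), OBO_NS_MAP)
  for (dag in dags) {
    for (id in dag$ids) {
      out <- c("[Term]",
               paste0("id: ", id),
               paste0("name: ", dag$names[[id]]),
               paste0("namespace: ", rev_ns[[dag$namespace]]))
      alts <- names(dag$alt_ids)[dag$alt_ids == id]
      out <- c(out, paste0("alt_id: ", sort(alts)))
      e <- dag$edges[dag$edges$child == id, , drop = FALSE]
      if (nrow(e)) {
        e <- e[order(e$parent), , drop = FALSE]
        rel_line <- ifelse(e$relation == "is_a",
                           paste0("is_a: ", e$parent),
                           paste0("relationship: ", e$relation, " ", e$parent))
        out <- c(out, rel_line)
      }
      writeLines(c(out, ""), con)
    }
  }
  invisible(path)
}
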