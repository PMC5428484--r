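# Independent oracles: brute-force implementations kept deliberately
# separate from the package's code paths.

# reflexive-transitive ancestor closure by naive DFS over the edge list
oracle_ancestors <- function(dag, term) {
  seen <- character(0)
  stack <- term
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, dag$edges$parent[dag$edges$child == v])
  }
  sort(seen)
}

# boolean matrix-power reachability closure (includes self)
oracle_ancestors_matrix <- function(dag) {
  ids <- dag$ids
  n <- length(ids)
  A <- diag(n) > 0
  dimnames(A) <- list(ids, ids)
  A[cbind(dag$edges$child, dag$edges$parent)] <- TRUE
  repeat {
    A2 <- (A %*% A) > 0 | A
    if (identical(A2, A)) break
    A <- A2
  }
  A
}

# descendant set of a term by scanning every term's oracle ancestors
oracle_descendants <- function(dag, term) {
  ids <- dag$ids
  ids[vapply(ids, function(t) term %in% oracle_ancestors(dag, t), logical(1))]
}

# N(t): distinct proteins directly annotated to t or any descendant
oracle_term_count <- function(dag, direct, term) {
  desc <- oracle_descendants(dag, term)
  length(Filter(function(ts) any(ts %in% desc), direct))
}

# straight-from-formula semantic similarity, written against the stated
# equations (not the package's code)
oracle_sim <- function(dag, ic, s, t, measure) {
  S <- intersect(oracle_ancestors(dag, s), oracle_ancestors(dag, t))
  I <- ic$I
  Iv <- I[S][!is.na(I[S])]
  Imica <- if (length(Iv)) max(Iv) else 0
  Is <- I[[s]]; It <- I[[t]]
  if (is.na(Is) || is.na(It)) return(0)
  if (measure == "simRes") return(Imica)
  if (measure == "simJC") return(1 / (1 + Is + It - 2 * Imica))
  if (measure == "simGIC") {
    U <- union(oracle_ancestors(dag, s), oracle_ancestors(dag, t))
    den <- sum(I[U], na.rm = TRUE)
    return(if (den == 0) 0 else sum(I[S], na.rm = TRUE) / den)
  }
  if (Is + It == 0) return(0)
  if (measure == "simLin") return(2 * Imica / (Is + It))
  if (measure == "simRel") {
    ok <- S[!is.na(I[S])]
    if (length(ok) == 0) return(0)
    return(max(2 * I[ok] / (Is + It) * (1 - ic$P[ok])))
  }
  if (measure == "simIC")
    return(2 * Imica / (Is + It) * (1 - 1 / (1 + Imica)))
  stop("unknown measure")
}

# shared small world for tests that only need "some valid world"
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(n_terms = c(BP = 20, MF = 10, CC = 8),
                           n_proteins = c(30, 30), n_orthologs = 12,
                           seed = 101)
      cache <<- make_world(spec)
    }
    cache
  }
})

tiny_ctx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- tiny_world()
      cache <<- suppressMessages(load_context(w$paths$obo, w$paths$gaf))
    }
    cache
  }
})

# hand-written three-term chain ontology: root <- A <- B
chain_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid",
    "namespace: biological_process", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: leaf",
    "namespace: biological_process", "is_a: GO:0000002", ""), path)
  path
}

# minimal GAF writer for toy corpora: rows of (protein, term, evidence,
# taxon [, qualifier])
toy_gaf <- function(rows, path = tempfile(fileext = ".gaf")) {
  lines <- vapply(rows, function(r) {
    q <- if (length(r) >= 5) r[[5]] else ""
    sprintf("FIX\t%s\t%s\t%s\t%s\tFIX:1\t%s\t\tP\t\t\tprotein\ttaxon:%s\t20250101\tFIX\t\t",
            r[[1]], r[[1]], q, r[[2]], r[[3]], r[[4]])
  }, character(1))
  writeLines(c("!gaf-version: 2.2", lines), path)
  path
}
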