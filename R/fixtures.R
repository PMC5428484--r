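#' Specification of a synthetic two-organism GO world
#'
#' Parameters for [make_world()], which writes a synthetic ontology
#' (OBO), per-organism annotation corpora (GAF 2.2), and an orthologue
#' pair list (TSV). The generator emulates the statistical structure the
#' scoring pipeline is designed for:
#'
#' * random single-root DAGs per namespace;
#' * heavy-tailed annotation counts — most proteins carry a handful of
#'   terms, a small "disease-gene-like" tail carries `tail_size`-plus
#'   terms, producing annotation bias;
#' * tail proteins preferentially annotated to shallow (near-root) terms,
#'   so their raw similarity to everything is inflated — the situation
#'   background z-scores exist to correct;
#' * a fraction of proteins annotated only with evidence code IEA, so
#'   IEA-excluded corpora lose exactly those proteins;
#' * planted one-to-one orthologues whose annotation sets overlap by
#'   `ortholog_overlap`, giving cases strictly higher expected similarity
#'   than derangement controls;
#' * a fraction of orthologue pairs flagged with >= 80% sequence
#'   identity, exercised by the reader's exclusion rule.
#'
#' @param n_terms named integer vector, terms per namespace.
#' @param max_parents maximum parents per non-root term.
#' @param n_proteins integer vector of length 2, proteins per organism.
#' @param taxa integer vector of length 2, synthetic taxon ids.
#' @param annot_rate mean number of terms per protein per annotated
#'   namespace for the low-count majority (Poisson, shifted so every
#'   annotated protein has at least one term).
#' @param tail_fraction fraction of proteins in the heavily annotated
#'   tail.
#' @param tail_size baseline term count for tail proteins.
#' @param iea_only_fraction fraction of proteins all of whose
#'   annotations carry evidence code IEA.
#' @param p_annotated named vector: probability a protein is annotated
#'   in each namespace (BP is 1 so every protein is scorable there).
#' @param n_orthologs number of planted orthologue pairs.
#' @param ortholog_overlap fraction of the first organism's terms copied
#'   into the orthologue partner's annotation.
#' @param high_identity_fraction fraction of orthologue pairs given
#'   >= 80% sequence identity (excluded by [read_orthologs()]).
#' @param part_of_fraction fraction of DAG edges typed `part_of`
#'   instead of `is_a`.
#' @param seed integer seed; the whole world is bit-reproducible.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_terms = c(BP = 40, MF = 20, CC = 12),
                         max_parents = 3,
                         n_proteins = c(60, 60),
                         taxa = c(9601L, 9602L),
                         annot_rate = 2.5,
                         tail_fraction = 0.1,
                         tail_size = 15,
                         iea_only_fraction = 0.25,
                         p_annotated = c(BP = 1, MF = 0.85, CC = 0.7),
                         n_orthologs = 25,
                         ortholog_overlap = 0.6,
                         high_identity_fraction = 0.1,
                         part_of_fraction = 0.15,
                         seed = 42) {
  spec <- list(n_terms = n_terms, max_parents = max_parents,
               n_proteins = n_proteins, taxa = taxa,
               annot_rate = annot_rate, tail_fraction = tail_fraction,
               tail_size = tail_size,
               iea_only_fraction = iea_only_fraction,
               p_annotated = p_annotated, n_orthologs = n_orthologs,
               ortholog_overlap = ortholog_overlap,
               high_identity_fraction = high_identity_fraction,
               part_of_fraction = part_of_fraction, seed = seed)
  validate_fixture_spec(spec)
  structure(spec, class = "fixture_spec")
}

validate_fixture_spec <- function(spec) {
  if (any(spec$n_terms < 2))
    stop_gofunsim("fixture spec invalid: every namespace needs >= 2 terms")
  if (spec$max_parents >= min(spec$n_terms))
    stop_gofunsim("fixture spec invalid: max_parents (%d) must be below the smallest namespace size (%d)",
                  spec$max_parents, min(spec$n_terms))
  if (spec$n_orthologs > min(spec$n_proteins))
    stop_gofunsim("fixture spec invalid: more orthologues (%d) than proteins (%d)",
                  spec$n_orthologs, min(spec$n_proteins))
  if (length(spec$n_proteins) != 2 || length(spec$taxa) != 2)
    stop_gofunsim("fixture spec invalid: exactly two organisms are modelled")
  invisible(spec)
}

#' Generate a synthetic ontology + corpus + orthology world
#'
#' Writes the standard-format files every reader in the package consumes
#' (OBO ontology, one GAF per organism, orthologue TSV) together with a
#' truth record holding every direct annotation, the planted orthology,
#' and per-protein term counts — the oracle against which parser and
#' scorer tests are checked.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @return list with `paths` (obo, gaf — length 2, orthologs), `truth`
#'   (records data.frame, direct sets, orthologs data.frame, iea_only
#'   ids, term depths), and `spec`.
#' @export
make_world <- function(spec, dir = tempfile("gofunsim_world")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  ## --- ontology -----------------------------------------------------
  dags <- list()
  depths <- list()
  counter <- 0L
  for (ns in names(spec$n_terms)) {
    nt <- spec$n_terms[[ns]]
    ids <- sprintf("GO:%07d", counter + seq_len(nt))
    counter <- counter + nt
    edges <- NULL
    depth <- stats::setNames(integer(nt), ids)
    for (i in seq_len(nt)[-1]) {
      np <- sample.int(min(spec$max_parents, i - 1), 1)
      parents <- sample(ids[seq_len(i - 1)], np)
      rel <- ifelse(stats::runif(np) < spec$part_of_fraction,
                    "part_of", "is_a")
      edges <- rbind(edges, data.frame(child = ids[i], parent = parents,
                                       relation = rel))
      depth[i] <- min(depth[parents]) + 1L
    }
    nm <- stats::setNames(sprintf("%s term %d", ns, seq_len(nt)), ids)
    dags[[ns]] <- new_go_dag(ns, ids, nm, edges)
    depths[[ns]] <- depth
  }
  obo_path <- file.path(dir, "ontology.obo")
  write_obo(dags, obo_path)

  ## --- proteins and annotations ------------------------------------
  org_prefix <- c("A", "B")
  proteins <- lapply(1:2, function(o)
    sprintf("%s%04d", org_prefix[o], seq_len(spec$n_proteins[o])))

  # orthologue partners: first n_orthologs of organism 1 paired with
  # first n_orthologs of organism 2
  n_orth <- spec$n_orthologs
  orth <- data.frame(idA = proteins[[1]][seq_len(n_orth)],
                     idB = proteins[[2]][seq_len(n_orth)])

  draw_count <- function(is_tail) {
    if (is_tail) spec$tail_size + stats::rpois(1, 5)
    else 1L + stats::rpois(1, max(spec$annot_rate - 1, 0))
  }
  # tail (heavily annotated) proteins favour shallow terms near the root
  draw_terms <- function(ns, count, is_tail) {
    pool <- dags[[ns]]$ids[-match(dags[[ns]]$root, dags[[ns]]$ids)]
    count <- min(count, length(pool))
    w <- if (is_tail) 1 / (1 + depths[[ns]][pool]) else rep(1, length(pool))
    sample(pool, count, prob = w)
  }

  records <- list()
  direct <- list()   # [[org]][[ns]][[protein]] -> terms
  tail_flag <- list()
  iea_only <- list()
  for (o in 1:2) {
    ids <- proteins[[o]]
    tail_flag[[o]] <- stats::runif(length(ids)) < spec$tail_fraction
    iea_only[[o]] <- ids[stats::runif(length(ids)) < spec$iea_only_fraction]
    direct[[o]] <- lapply(stats::setNames(NAMESPACES, NAMESPACES),
                          function(ns) list())
  }

  for (o in 1:2) {
    for (i in seq_along(proteins[[o]])) {
      p <- proteins[[o]][i]
      for (ns in names(spec$n_terms)) {
        if (stats::runif(1) > spec$p_annotated[[ns]]) next
        if (o == 2 && p %in% orth$idB) {
          # partner annotation: shared core + own extras
          a_terms <- direct[[1]][[ns]][[orth$idA[match(p, orth$idB)]]]
          if (is.null(a_terms)) next
          n_share <- round(spec$ortholog_overlap * length(a_terms))
          shared <- if (n_share > 0) sample(a_terms, n_share) else character(0)
          extra <- draw_terms(ns, draw_count(tail_flag[[o]][i]), FALSE)
          n_extra <- max(1, length(a_terms) - n_share)
          terms <- unique(c(shared, utils::head(extra, n_extra)))
        } else {
          terms <- unique(draw_terms(ns, draw_count(tail_flag[[o]][i]),
                                     tail_flag[[o]][i]))
        }
        if (length(terms) == 0) next
        direct[[o]][[ns]][[p]] <- sort(terms)
        ev <- if (p %in% iea_only[[o]]) rep("IEA", length(terms))
              else sample(c("EXP", "IDA", "IMP", "ISS"), length(terms),
                          replace = TRUE)
        records[[length(records) + 1L]] <-
          data.frame(protein = p, term = sort(terms), evidence = ev,
                     taxon = spec$taxa[o], namespace = ns, organism = o)
      }
    }
  }
  records <- do.call(rbind, records)

  ## --- write GAFs ---------------------------------------------------
  aspect <- c(BP = "P", MF = "F", CC = "C")
  gaf_paths <- character(2)
  for (o in 1:2) {
    r <- records[records$organism == o, , drop = FALSE]
    lines <- sprintf("FIX\t%s\t%s\t%s\t%s\tFIX:0000001\t%s\t\t%s\t\t\tprotein\ttaxon:%d\t20250101\tFIX\t\t",
                     r$protein, r$protein,
                     c(BP = "involved_in", MF = "enables",
                       CC = "located_in")[r$namespace],
                     r$term, r$evidence, aspect[r$namespace], r$taxon)
    gaf_paths[o] <- file.path(dir, sprintf("organism%d.gaf", o))
    writeLines(c("!gaf-version: 2.2", lines), gaf_paths[o])
  }

  ## --- orthologue list ----------------------------------------------
  high <- stats::runif(n_orth) < spec$high_identity_fraction
  orth$pct_identity <- round(ifelse(high, stats::runif(n_orth, 80, 95),
                                    stats::runif(n_orth, 30, 75)), 1)
  orth_path <- file.path(dir, "orthologs.tsv")
  utils::write.table(orth, orth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(paths = list(obo = obo_path, gaf = gaf_paths,
                    orthologs = orth_path),
       truth = list(records = records,
                    direct = stats::setNames(direct, c("org1", "org2")),
                    orthologs = orth,
                    iea_only = stats::setNames(iea_only, c("org1", "org2")),
                    depths = depths,
                    tail_proteins = stats::setNames(
                      lapply(1:2, function(o) proteins[[o]][tail_flag[[o]]]),
                      c("org1", "org2"))),
       spec = spec)
}
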