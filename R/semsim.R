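SS_MEASURES <- c("simRes", "simLin", "simRel", "simIC", "simJC", "simGIC")

#' Most informative common ancestor of two terms
#'
#' The MICA is the common ancestor of `s` and `t` with maximal information
#' content. Ancestor sets are reflexive, so the MICA of a term with itself
#' is the term. Ties in information content are broken by the
#' lexicographically smallest term id, making runs reproducible.
#'
#' @param dag a `go_dag`; both terms must belong to its namespace.
#' @param ic the matching `go_ic`.
#' @param s,t term ids.
#' @return a list with `s`, `t`, `common_ancestors`, `mica`, `I_s`, `I_t`,
#'   `I_mica`, `P_mica`.
#' @export
mica <- function(dag, ic, s, t) {
  stopifnot(inherits(dag, "go_dag"), inherits(ic, "go_ic"))
  if (!identical(dag$namespace, ic$namespace))
    stop_gofunsim("dag namespace (%s) and IC namespace (%s) differ",
                  dag$namespace, ic$namespace)
  as_ <- go_ancestors(dag, s)   # errors on cross-namespace / unknown ids
  at_ <- go_ancestors(dag, t)
  common <- intersect(as_, at_)
  Ic <- ic$I[common]
  ok <- !is.na(Ic)
  if (any(ok)) {
    imax <- max(Ic[ok])
    cand <- sort(common[ok][Ic[ok] == imax])
    m <- cand[1]
    im <- imax
    pm <- unname(ic$P[m])
  } else {
    m <- NA_character_; im <- NA_real_; pm <- NA_real_
  }
  structure(list(s = s, t = t, common_ancestors = sort(common),
                 mica = m, I_s = unname(ic$I[s]), I_t = unname(ic$I[t]),
                 I_mica = im, P_mica = pm),
            class = "go_termpair")
}

#' Pairwise term semantic similarity
#'
#' Six classic information-content measures over a pair of GO terms in one
#' namespace. With `S(s,t)` the set of common ancestors, `I` the
#' information content and `c*` the most informative common ancestor
#' (MICA):
#'
#' * `simRes` = I(c*)
#' * `simLin` = 2 I(c*) / (I(s) + I(t))
#' * `simRel` = max over c in S(s,t) of \[2 I(c)/(I(s)+I(t))\] (1 - P(c)),
#'   jointly maximized over all common ancestors (not only at the MICA);
#'   `simrel_all_ancestors = FALSE` gives the MICA-only variant.
#' * `simIC`  = simLin * (1 - 1/(1 + I(c*)))
#' * `simJC`  = 1 / (1 + I(s) + I(t) - 2 I(c*))
#' * `simGIC` = sum of I over ancestors(s) intersect ancestors(t) divided
#'   by the sum over ancestors(s) union ancestors(t)
#'
#' All measures except `simRes` lie in \[0, 1\]. The degenerate case
#' I(s) + I(t) = 0 (both terms annotated to every protein) returns 0 for
#' the ratio measures. Terms with no annotated protein are unscorable and
#' score 0 against everything, with a warning.
#'
#' @param dag a `go_dag`.
#' @param ic the matching `go_ic`.
#' @param s,t term ids in `dag`'s namespace.
#' @param measure one of `"simRes"`, `"simLin"`, `"simRel"`, `"simIC"`,
#'   `"simJC"`, `"simGIC"`.
#' @param simrel_all_ancestors maximize the Schlicker relevance weight over
#'   all common ancestors (default) or evaluate it only at the MICA.
#' @param simic_variant `"standard"` uses the original information
#'   coefficient weight (1 - 1/(1 + I(c*))), which keeps scores in
#'   \[0, 1\]; `"as_printed"` uses the (1 - 1/(1 - I(c*))) form for
#'   comparison, which is not a bounded similarity.
#' @return a single numeric score.
#' @export
term_sim <- function(dag, ic, s, t,
                     measure = c("simRes", "simLin", "simRel",
                                 "simIC", "simJC", "simGIC"),
                     simrel_all_ancestors = TRUE,
                     simic_variant = c("standard", "as_printed")) {
  measure <- match.arg(measure)
  simic_variant <- match.arg(simic_variant)
  anc <- ancestor_table(dag)
  if (is.null(anc[[s]]))
    stop_gofunsim("unknown term id '%s' in namespace %s", s, dag$namespace)
  if (is.null(anc[[t]]))
    stop_gofunsim("unknown term id '%s' in namespace %s", t, dag$namespace)
  v <- term_sim_cell(anc[[s]], anc[[t]], ic, s, t, measure,
                     simrel_all_ancestors, simic_variant)
  if (is.na(v)) {
    warning(sprintf("unscorable term pair (%s, %s): no annotation support; scoring 0",
                    s, t))
    v <- 0
  }
  v
}

# core formula evaluation on precomputed ancestor sets; returns NA when a
# term is unscorable (caller decides whether to warn)
term_sim_cell <- function(anc_s, anc_t, ic, s, t, measure,
                          simrel_all_ancestors = TRUE,
                          simic_variant = "standard") {
  Is <- ic$I[[s]]; It <- ic$I[[t]]
  if (is.na(Is) || is.na(It)) return(NA_real_)
  common <- intersect(anc_s, anc_t)
  Ic <- ic$I[common]
  keep <- !is.na(Ic)
  common <- common[keep]; Ic <- Ic[keep]
  Im <- if (length(Ic)) max(Ic) else 0
  denom <- Is + It

  switch(measure,
    simRes = Im,
    simLin = if (denom == 0) 0 else 2 * Im / denom,
    simRel = {
      if (denom == 0 || length(Ic) == 0) 0
      else if (simrel_all_ancestors)
        max(2 * Ic / denom * (1 - ic$P[common]))
      else {
        cand <- sort(common[Ic == Im])[1]
        2 * Im / denom * (1 - ic$P[[cand]])
      }
    },
    simIC = {
      if (denom == 0) 0
      else if (simic_variant == "standard")
        2 * Im / denom * (1 - 1 / (1 + Im))
      else
        2 * Im / denom * (1 - 1 / (1 - Im))
    },
    # grouped so that s = t gives exactly 1 in floating point
    simJC = 1 / (1 + (Is - Im) + (It - Im)),
    simGIC = {
      un <- union(anc_s, anc_t)
      su <- sum(ic$I[un], na.rm = TRUE)
      if (su == 0) 0 else sum(Ic) / su
    })
}

#' All-pairs term similarity matrix
#'
#' Evaluates [term_sim()] over the cartesian product of two term vectors.
#' Unscorable pairs (involving a term with no annotation support) score 0
#' and are reported once via a warning with their count.
#'
#' @inheritParams term_sim
#' @param terms1,terms2 character vectors of term ids (rows / columns).
#' @param ... passed on to the measure (`simrel_all_ancestors`,
#'   `simic_variant`).
#' @return numeric matrix with `terms1` as rownames, `terms2` as colnames.
#' @export
term_sim_matrix <- function(dag, ic, terms1, terms2, measure, ...) {
  anc <- ancestor_table(dag)
  missing <- setdiff(c(terms1, terms2), names(anc))
  if (length(missing))
    stop_gofunsim("unknown term id(s) in namespace %s: %s", dag$namespace,
                  paste(utils::head(missing, 5), collapse = ", "))
  M <- matrix(NA_real_, length(terms1), length(terms2),
              dimnames = list(terms1, terms2))
  for (i in seq_along(terms1))
    for (j in seq_along(terms2))
      M[i, j] <- term_sim_cell(anc[[terms1[i]]], anc[[terms2[j]]], ic,
                               terms1[i], terms2[j], measure, ...)
  n_unscorable <- sum(is.na(M))
  if (n_unscorable > 0) {
    warning(sprintf("%d unscorable term pair(s) scored 0 (no annotation support)",
                    n_unscorable))
    M[is.na(M)] <- 0
  }
  M
}
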