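test_that("NOT-qualified GAF lines are dropped", {
  dags <- parse_obo(chain_obo())
  gaf <- toy_gaf(list(
    list("P1", "GO:0000003", "EXP", 9601),
    list("P2", "GO:0000003", "EXP", 9601, "NOT|involved_in")))
  corpus <- parse_gaf(gaf, dags)
  expect_equal(nrow(corpus$records), 1)
  expect_equal(corpus$records$protein, "P1")
})

test_that("empty GAF yields an empty corpus without error", {
  dags <- parse_obo(chain_obo())
  path <- tempfile(fileext = ".gaf")
  writeLines("!gaf-version: 2.2", path)
  corpus <- parse_gaf(path, dags)
  expect_s3_class(corpus, "go_corpus")
  expect_equal(nrow(corpus$records), 0)
})

test_that("wrong column counts are a format error naming the line", {
  dags <- parse_obo(chain_obo())
  path <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2", "only\tthree\tcolumns"), path)
  expect_error(parse_gaf(path, dags), "line 2")
})

test_that("unknown and alt_id terms are handled", {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: leaf", "alt_id: GO:0008888",
    "namespace: biological_process", "is_a: GO:0000001", ""), path)
  dags <- parse_obo(path)
  gaf <- toy_gaf(list(
    list("P1", "GO:0008888", "EXP", 9601),   # alt id -> GO:0000002
    list("P2", "GO:7777777", "EXP", 9601)))  # unknown -> dropped
  expect_message(corpus <- parse_gaf(gaf, dags), "dropped 1")
  expect_equal(corpus$records$term, "GO:0000002")
  expect_equal(corpus$n_dropped, 1)
})

test_that("fixture GAF reproduces the generator's truth record", {
  w <- tiny_world()
  dags <- parse_obo(w$paths$obo)
  corpus <- parse_gaf(w$paths$gaf[1], dags)
  truth <- w$truth$direct$org1
  for (ns in names(truth)) {
    expect_equal(corpus$direct[[ns]][names(truth[[ns]])], truth[[ns]])
  }
  # record multiset matches exactly
  got <- corpus$records[order(corpus$records$protein, corpus$records$term,
                              corpus$records$namespace), ]
  want <- w$truth$records[w$truth$records$organism == 1, ]
  want <- want[order(want$protein, want$term, want$namespace), ]
  expect_equal(got$term, want$term)
  expect_equal(got$evidence, want$evidence)
  expect_equal(unique(got$taxon), w$spec$taxa[1])
})

test_that("IEA and taxon filters behave as defined", {
  dags <- parse_obo(chain_obo())
  gaf <- toy_gaf(list(
    list("P1", "GO:0000003", "IEA", 9601),
    list("P2", "GO:0000003", "EXP", 9601),
    list("P3", "GO:0000002", "IDA", 9602)))
  corpus <- parse_gaf(gaf, dags)

  no_iea <- filter_corpus(corpus, iea = "excluded")
  expect_false("IEA" %in% no_iea$records$evidence)
  expect_equal(sort(no_iea$records$protein), c("P2", "P3"))

  aoo <- filter_corpus(corpus, taxa = 9601)
  expect_equal(sort(unique(aoo$records$taxon)), 9601)
  expect_equal(sort(aoo$records$protein), c("P1", "P2"))

  expect_warning(
    empty <- filter_corpus(parse_gaf(toy_gaf(list(
      list("P1", "GO:0000003", "IEA", 9601))), dags), iea = "excluded"),
    "empty")
  expect_equal(nrow(empty$records), 0)
})

test_that("IEA-excluded fixture corpus keeps exactly the non-IEA-only proteins", {
  w <- tiny_world()
  dags <- parse_obo(w$paths$obo)
  corpus <- parse_gaf(w$paths$gaf[1], dags)
  filtered <- filter_corpus(corpus, iea = "excluded")
  all_prot <- unique(corpus$records$protein)
  expect_setequal(unique(filtered$records$protein),
                  setdiff(all_prot, w$truth$iea_only$org1))
  # and the fixture records its own non-IEA count
  expect_equal(nrow(filtered$records),
               sum(w$truth$records$organism == 1 &
                     w$truth$records$evidence != "IEA"))
})

test_that("information content matches brute-force descendant counting", {
  w <- tiny_world()
  dags <- parse_obo(w$paths$obo)
  corpus <- suppressMessages(
    new_corpus <- parse_gaf(w$paths$gaf[1], dags))
  for (ns in c("BP", "MF")) {
    dag <- dags[[ns]]
    ic <- build_ic(corpus, dag)
    direct <- corpus$direct[[ns]]
    for (t in dag$ids)
      expect_equal(unname(ic$N[t]), oracle_term_count(dag, direct, t),
                   label = paste("N of", t))
    expect_equal(unname(ic$P[dag$root]), 1)
    expect_equal(unname(ic$I[dag$root]), 0)
    # monotone along every edge: parents at least as probable
    ok <- ic$N[dag$edges$parent] >= ic$N[dag$edges$child]
    expect_true(all(ok))
    expect_true(all(ic$P >= 0 & ic$P <= 1))
    expect_true(all(ic$I[!is.na(ic$I)] >= 0))
  }
})

test_that("forced tiny IC examples come out exactly", {
  dags <- parse_obo(chain_obo())
  # one protein on the leaf of a chain: every N is 1, every I is 0
  corpus <- parse_gaf(toy_gaf(list(list("P1", "GO:0000003", "EXP", 9601))),
                      dags)
  ic <- build_ic(corpus, dags$BP)
  expect_equal(unname(ic$N), c(1L, 1L, 1L))
  expect_equal(unname(ic$I), c(0, 0, 0))

  # two proteins on sibling leaves under root
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: s1",
    "namespace: biological_process", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: s2",
    "namespace: biological_process", "is_a: GO:0000001", ""), path)
  dags2 <- parse_obo(path)
  corpus2 <- parse_gaf(toy_gaf(list(
    list("P1", "GO:0000002", "EXP", 9601),
    list("P2", "GO:0000003", "EXP", 9601))), dags2)
  ic2 <- build_ic(corpus2, dags2$BP)
  expect_equal(unname(ic2$P["GO:0000002"]), 0.5)
  expect_equal(unname(ic2$I["GO:0000002"]), log(2))
  expect_equal(unname(ic2$I["GO:0000001"]), 0)
})

test_that("distinct-protein counting ignores multiple descendant annotations", {
  dags <- parse_obo(chain_obo())
  # one protein annotated to both mid and leaf: N(root) still 1
  corpus <- parse_gaf(toy_gaf(list(
    list("P1", "GO:0000002", "EXP", 9601),
    list("P1", "GO:0000003", "EXP", 9601))), dags)
  ic <- build_ic(corpus, dags$BP)
  expect_equal(unname(ic$N["GO:0000001"]), 1L)
  expect_equal(unname(ic$N["GO:0000002"]), 1L)

  # adding a protein never decreases any count
  corpus2 <- parse_gaf(toy_gaf(list(
    list("P1", "GO:0000002", "EXP", 9601),
    list("P1", "GO:0000003", "EXP", 9601),
    list("P2", "GO:0000003", "EXP", 9601))), dags)
  ic2 <- build_ic(corpus2, dags$BP)
  expect_true(all(ic2$N >= ic$N))
})

test_that("IC of a filtered corpus is relative to its own root count", {
  w <- tiny_world()
  dags <- parse_obo(w$paths$obo)
  corpus <- parse_gaf(w$paths$gaf[1], dags)
  filtered <- filter_corpus(corpus, iea = "excluded")
  ic <- build_ic(filtered, dags$BP)
  expect_equal(ic$n_root, length(unique(
    filtered$records$protein[filtered$records$namespace == "BP"])))
  expect_equal(unname(ic$P[dags$BP$root]), 1)
})

test_that("build_ic errors on a namespace with no annotations", {
  dags <- parse_obo(chain_obo())
  path <- tempfile(fileext = ".gaf")
  writeLines("!gaf-version: 2.2", path)
  corpus <- parse_gaf(path, dags)
  expect_error(build_ic(corpus, dags$BP), "no annotated proteins")
})

test_that("write_ic exports a readable TSV", {
  w <- tiny_world()
  ctx <- tiny_ctx()
  path <- tempfile(fileext = ".tsv")
  write_ic(ctx$ics$BP, path)
  df <- read.delim(path)
  expect_equal(nrow(df), length(ctx$ics$BP$N))
  expect_equal(df$N[match(ctx$dags$BP$root, df$term)], ctx$ics$BP$n_root)
})
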