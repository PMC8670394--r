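# Knowledge-base data model: file round trips, merging, extraction,
# classification.

test_that("an empty axiom file loads as an empty knowledge base", {
  f <- withr::local_tempfile(fileext = ".kb")
  writeLines(c("# only a comment", ""), f)
  kb <- read_kb(f)
  expect_equal(kb_n_entities(kb), 0L)
  expect_equal(kb_n_axioms(kb), 0L)
})

test_that("the packaged DM core contains its top-level classes", {
  kb <- load_dm_core()
  for (cls in c("Algorithm", "Characteristics", "INPUT", "Parameter", "Process"))
    expect_true(kb_has_entity(kb, cls))
  expect_true(all(kb$entities$kind %in%
    c("class", "object-property", "data-property", "individual")))
})

test_that("parse errors report the line number and dangling kinds conflict", {
  f <- withr::local_tempfile(fileext = ".kb")
  writeLines(c("SUBCLASSOF\tA\tB", "RESTRICTION\tA\tmissingfiller"), f)
  expect_error(read_kb(f), "line 2")
  # same name used as class and as object-property
  f2 <- withr::local_tempfile(fileext = ".kb")
  writeLines(c("SUBCLASSOF\tA\tB", "SUBPROP\tA\tQ"), f2)
  expect_error(read_kb(f2), "kind conflict")
})

test_that("save then load is the identity on random knowledge bases", {
  set.seed(42)
  for (rep in 1:5) {
    kb <- random_kb(n_classes = 12, n_props = 3, n_sub = 20, n_res = 10,
                    n_ind = 4, n_type = 5, n_prop_ax = 3)
    f <- withr::local_tempfile(fileext = ".kb")
    write_kb(kb, f)
    kb2 <- read_kb(f, namespace = kb$namespace)
    expect_equal(kb2$entities, kb$entities)
    expect_equal(abstate:::kb_canonical_axioms(kb2), abstate:::kb_canonical_axioms(kb))
  }
})

test_that("declared isolated entities survive the file round trip", {
  kb <- knowledge_base(axiom_table(subclass = c("A", "B")),
                       declare = data.frame(name = "Lonely", kind = "class"))
  f <- withr::local_tempfile(fileext = ".kb")
  write_kb(kb, f)
  expect_true(kb_has_entity(read_kb(f), "Lonely"))
})

test_that("merging empty knowledge bases yields an empty knowledge base", {
  e <- knowledge_base()
  m <- kb_merge(e, e, "new")
  expect_equal(kb_n_axioms(m), 0L)
  expect_equal(m$namespace, "new")
})

test_that("merging rewrites namespaces, unifies shared names and keeps all axioms", {
  m <- kb_merge(load_dm_core(), load_medical_domain(), "merged")
  for (cls in c("MedicalDataAnalysisTask", "MedicalData", "Algorithm",
                "Characteristics", "INPUT", "Parameter", "Process"))
    expect_true(kb_has_entity(m, cls))
  expect_equal(m$namespace, "merged")
  # signature conservation: merged signature is the union of input signatures
  expect_setequal(m$entities$name,
                  union(load_dm_core()$entities$name,
                        load_medical_domain()$entities$name))
})

test_that("merging disjoint-signature KBs adds axiom counts exactly", {
  set.seed(7)
  for (rep in 1:5) {
    a <- random_kb(n_classes = 8, n_sub = 10, n_res = 5)
    b <- random_kb(n_classes = 8, n_sub = 10, n_res = 5)
    b$entities$name <- sub("^C", "D", b$entities$name)
    b$entities$name <- sub("^P", "Q", b$entities$name)
    for (col in c("s", "p", "o")) {
      b$axioms[[col]] <- sub("^C", "D", b$axioms[[col]])
      b$axioms[[col]] <- sub("^P", "Q", b$axioms[[col]])
    }
    m <- kb_merge(a, b, "m")
    expect_equal(kb_n_axioms(m), kb_n_axioms(a) + kb_n_axioms(b))
    # every input axiom appears in the merge
    expect_true(all(do.call(paste, abstate:::kb_canonical_axioms(a)) %in%
                    do.call(paste, abstate:::kb_canonical_axioms(m))))
  }
})

test_that("same local name with different kinds is a unification conflict", {
  a <- knowledge_base(axiom_table(subclass = c("X", "Top")))
  b <- knowledge_base(axiom_table(subprop = c("X", "P0")))
  expect_error(kb_merge(a, b, "m"), "unification conflict.*X")
})

test_that("extraction returns a sub-KB, keeps the seed, and is idempotent", {
  m <- load_merged_kb()
  sub <- kb_extract(m, "ConsistencyAnalysis")
  expect_true(all(sub$entities$name %in% m$entities$name))
  expect_true(all(do.call(paste, abstate:::kb_canonical_axioms(sub)) %in%
                  do.call(paste, abstate:::kb_canonical_axioms(m))))
  expect_true(kb_has_entity(sub, "ConsistencyAnalysis"))
  sub2 <- kb_extract(sub, "ConsistencyAnalysis")
  expect_equal(sort(sub2$entities$name), sort(sub$entities$name))
  expect_equal(abstate:::kb_canonical_axioms(sub2), abstate:::kb_canonical_axioms(sub))
})

test_that("extraction keeps descriptive algorithms and drops unrelated ones", {
  sub <- kb_extract(load_merged_kb(), "ConsistencyAnalysis")
  expect_true(kb_has_entity(sub, "DescriptiveModelingAlgorithm"))
  expect_true(kb_has_entity(sub, "CF"))
  expect_true(kb_has_entity(sub, "Kupershtokh_Mirkin_Trofimov"))
  expect_false(kb_has_entity(sub, "classificationModelingAlgorithms"))
  expect_false(kb_has_entity(sub, "ClusteringModelingAlgorithm"))
  expect_false(kb_has_entity(sub, "BayesianAlgorithm"))
})

test_that("extracting an isolated class keeps only that class", {
  kb <- knowledge_base(axiom_table(subclass = c("A", "B")),
                       declare = data.frame(name = "Iso", kind = "class"))
  sub <- kb_extract(kb, "Iso")
  expect_equal(sub$entities$name, "Iso")
  expect_equal(kb_n_axioms(sub), 0L)
  expect_error(kb_extract(kb, "Nope"), "unknown task entity")
})

test_that("extraction matches an independent breadth-first reachability oracle", {
  set.seed(11)
  for (rep in 1:8) {
    kb <- random_kb(n_classes = 20, n_props = 4, n_sub = 25, n_res = 15,
                    n_ind = 5, n_type = 6, n_prop_ax = 4)
    seed_e <- sample(kb$entities$name[kb$entities$kind == "class"], 1)
    sub <- kb_extract(kb, seed_e)
    expect_equal(sort(sub$entities$name), extract_bfs_oracle(kb, seed_e))
  }
})

test_that("classification is transitive, reflexive and idempotent", {
  kb <- knowledge_base(axiom_table(subclass = rbind(c("A", "B"), c("B", "C"))))
  cl <- kb_classify(kb)
  expect_true("C" %in% cl$class_anc[["A"]])       # transitivity through B
  expect_true("A" %in% cl$class_anc[["A"]])       # reflexivity
  empty_cl <- kb_classify(knowledge_base())
  expect_length(empty_cl$class_anc, 0)
})

test_that("classification equals the matrix-power transitive closure on random DAGs", {
  set.seed(5)
  for (rep in 1:10) {
    kb <- random_kb(n_classes = 15, n_sub = 25, n_res = 0)
    cl <- kb_classify(kb)
    M <- closure_matrix_oracle(kb$entities$name[kb$entities$kind == "class"],
                               kb_subclass_edges(kb))
    for (x in rownames(M))
      expect_setequal(cl$class_anc[[x]], colnames(M)[M[x, ]])
  }
})

test_that("a subclass cycle is reported with its members", {
  kb <- knowledge_base(axiom_table(subclass = rbind(c("A", "B"), c("B", "C"),
                                                    c("C", "A"))))
  expect_error(kb_classify(kb), "cycle.*A.*B.*C|cycle.*B.*C.*A|cycle.*C.*A.*B")
})
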