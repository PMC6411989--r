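anat <- toy_anatomy()
path <- toy_pathology()

pc <- function(a, p) list(anatomy_id = a, pathology_id = p)

test_that("enumerate_pairs deduplicates and validates", {
  rec <- data.frame(
    mouse_id = c("m1", "m2", "m3"),
    anatomy_id = c("A:H", "A:H", "A:Lu"),
    pathology_id = c("P:Ad", "P:Ad", "P:I"))
  pairs <- enumerate_pairs(rec, anat, path)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(paste(pairs$anatomy_id, pairs$pathology_id),
                  c("A:H P:Ad", "A:Lu P:I"))
  expect_equal(nrow(enumerate_pairs(rec[0, ], anat, path)), 0L)
  rec$anatomy_id[2] <- "A:nope"
  expect_error(enumerate_pairs(rec, anat, path), "record 2")
})

test_that("pattern subsumption follows the per-kind structural rule", {
  # is_a on both sides: (H, Ad) under (H, N) because Ad is_a N
  expect_true(pattern_subsumes("MAP", anat, path,
                               pc("A:H", "P:N"), pc("A:H", "P:Ad")))
  # parthood only helps when the kind uses it: ventricle part_of heart
  expect_false(pattern_subsumes("MAP", anat, path,
                                pc("A:H", "P:Ad"), pc("A:V", "P:Ad")))
  expect_true(pattern_subsumes("MAPT", anat, path,
                               pc("A:H", "P:Ad"), pc("A:V", "P:Ad")))
  # PAMT: pathology is_a plus anatomy parthood
  expect_true(pattern_subsumes("PAMT", anat, path,
                               pc("A:H", "P:N"), pc("A:V", "P:Ad")))
  expect_false(pattern_subsumes("PAM", anat, path,
                                pc("A:H", "P:N"), pc("A:V", "P:Ad")))
})

test_that("compound IDs are deterministic functions of the pair", {
  expect_equal(compound_id("MAP", "A:H", "P:Ad"), "MAP:H-Ad")
  expect_equal(compound_id("PAMT", "MA:0000001", "MPATH:123"),
               "PAMT:0000001-123")
})

test_that("build attaches, classifies and reduces the union graph", {
  # single pair: direct parent is the backbone anatomy class
  co <- build_pattern_ontology(anat, path,
                               data.frame(anatomy_id = "A:H",
                                          pathology_id = "P:Ad"), "MAP")
  expect_equal(co$graph$parents_isa[["MAP:H-Ad"]], "A:H")

  # transitive reduction: (H, Ad) -> (H, N) -> H, and no (H, Ad) -> H edge
  co2 <- build_pattern_ontology(
    anat, path,
    data.frame(anatomy_id = c("A:H", "A:H"),
               pathology_id = c("P:Ad", "P:N")), "MAP")
  expect_equal(co2$graph$parents_isa[["MAP:H-Ad"]], "MAP:H-N")
  expect_equal(co2$graph$parents_isa[["MAP:H-N"]], "A:H")

  # parthood changes the pattern hierarchy only for the T kinds
  pairs <- data.frame(anatomy_id = c("A:V", "A:H"),
                      pathology_id = c("P:Ad", "P:Ad"))
  map <- build_pattern_ontology(anat, path, pairs, "MAP")
  mapt <- build_pattern_ontology(anat, path, pairs, "MAPT")
  expect_false("MAP:H-Ad" %in% map$graph$parents_isa[["MAP:V-Ad"]])
  expect_true("MAPT:H-Ad" %in% mapt$graph$parents_isa[["MAPT:V-Ad"]])

  # the union graph is one rooted DAG under the owl:Thing stand-in
  expect_equal(map$graph$root, "ROOT:thing")
  expect_error(build_pattern_ontology(anat, path, pairs[0, ], "MAP"),
               "empty pair set")
})

test_that("pathology-root pairs merge into their anatomy class (MAP/MAPT)", {
  pairs <- data.frame(anatomy_id = c("A:H", "A:H"),
                      pathology_id = c("P:R", "P:Ad"))
  co <- build_pattern_ontology(anat, path, pairs, "MAP")
  expect_equal(sum(co$pattern_classes$merged), 1L)
  expect_equal(co$pattern_classes$class_id[co$pattern_classes$merged], "A:H")
  expect_false("MAP:H-R" %in% co$graph$classes)
  expect_equal(attr(co$graph, "synonyms"), c("A:H" = "MAP:H-R"))
  # the merged node still subsumes the surviving pattern class
  expect_true(subsumes(co$graph, "A:H", "MAP:H-Ad"))
})

test_that("anatomy-root pairs merge into their pathology class (PAM/PAMT)", {
  pairs <- data.frame(anatomy_id = c("A:R", "A:H"),
                      pathology_id = c("P:Ad", "P:Ad"))
  co <- build_pattern_ontology(anat, path, pairs, "PAM")
  expect_equal(co$pattern_classes$class_id[co$pattern_classes$merged],
               "P:Ad")
  expect_true(subsumes(co$graph, "P:Ad", "PAM:H-Ad"))
})

test_that("pattern edge sets are nested and MAP/PAM orders are isomorphic", {
  for (seed in 1:6) {
    w <- random_world(seed)
    pairs <- enumerate_pairs(w$cohort$records, w$anatomy, w$pathology)
    if (nrow(pairs) < 2L) next
    built <- lapply(c(MAP = "MAP", MAPT = "MAPT", PAM = "PAM",
                      PAMT = "PAMT"), function(k)
      build_pattern_ontology(w$anatomy, w$pathology, pairs, k))
    rel <- lapply(built, function(co) {
      pcs <- co$pattern_classes
      outer(seq_len(nrow(pcs)), seq_len(nrow(pcs)),
            Vectorize(function(i, j) {
              graph_reaches(co$graph, pcs$class_id[j], pcs$class_id[i])
            }))
    })
    # parthood closure only adds subsumptions
    expect_true(all(rel$MAP <= rel$MAPT))
    expect_true(all(rel$PAM <= rel$PAMT))
    # backbone choice does not change the induced order on pattern classes
    expect_identical(rel$MAP, rel$PAM)
    expect_identical(rel$MAPT, rel$PAMT)
  }
})

test_that("transitive reduction plus closure recovers the full relation", {
  w <- random_world(11)
  pairs <- enumerate_pairs(w$cohort$records, w$anatomy, w$pathology)
  co <- build_pattern_ontology(w$anatomy, w$pathology, pairs, "MAPT")
  pcs <- co$pattern_classes
  for (i in seq_len(nrow(pcs))) {
    for (j in seq_len(nrow(pcs))) {
      expect_equal(
        graph_reaches(co$graph, pcs$class_id[i], pcs$class_id[j]),
        pattern_subsumes("MAPT", w$anatomy, w$pathology,
                         pc(pcs$anatomy_id[j], pcs$pathology_id[j]),
                         pc(pcs$anatomy_id[i], pcs$pathology_id[i])))
    }
  }
})
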