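pool_ontology <- function() read_obo(text = pool_to_obo())

# 10 instances: 3 occurrence-typed, 2 inferred (disjoint sets), mixed ages,
# diseases from both branches of the mini ontology.
fixture_store <- function() {
  make_store(list(
    make_instance("a_01", "a", 14, 16, rel = "AGE_OF_ONSET",
                  term = "DOID:0000011"),
    make_instance("b_01", "b", 12, 18, rel = "AGE_OF_DIAGNOSIS",
                  term = "DOID:0000012", gender = "MALE"),
    make_instance("c_01", "c", 17, 25, rel = "AGE_OF_OBSERVATION",
                  term = "DOID:0000015", pub_year = 1995L),
    make_instance("d_01", "d", 30, 40, rel = "AGE_OF_ONSET",
                  term = "DOID:0000021", curated = TRUE),
    make_instance("e_01", "e", 60, 60, rel = "AGE_OF_DIAGNOSIS",
                  term = "DOID:0000013",
                  redundant_terms = "DOID:0000002"),
    make_instance("f_01", "f", 0, 30, inferred = TRUE,
                  rel = "AGE_OF_ONSET", term = "DOID:0000022"),
    make_instance("g_01", "g", 70, 120, inferred = TRUE,
                  rel = "AGE_OF_DIAGNOSIS", term = "DOID:0000023"),
    make_instance("h_01", "h", 5, 10, rel = "AGE_OF_OCCURRENCE",
                  term = "DOID:0000024"),
    make_instance("i_01", "i", 45, 64, rel = "AGE_OF_OCCURRENCE",
                  term = "DOID:0000025", gender = "FEMALE"),
    make_instance("j_01", "j", 80, 90, rel = "AGE_OF_OCCURRENCE",
                  term = "DOID:0000014",
                  pub_types = c("Journal Article", "Review"))))
}

test_that("the population filter rejects undetermined and phenotype-free", {
  r <- make_record("A 59-year-old man was diagnosed with carcinoma.")
  m <- extract_age_mentions(r)
  snip <- build_snippet(r, m[1, , drop = FALSE], "AGE_OF_DIAGNOSIS")
  hits <- data.frame(source = "ONTOLOGY", id = "DOID:305",
                     mapped_ontology_id = NA_character_,
                     matched_span = "carcinoma", start = 1L, end = 9L,
                     is_redundant = FALSE, stringsAsFactors = FALSE)
  expect_null(assemble_instance(r, m[1, ], "UNDETERMINED", snip, hits, "MALE"))
  expect_null(assemble_instance(r, m[1, ], "AGE_OF_DIAGNOSIS", snip,
                                hits[0, ], "MALE"))
  inst <- assemble_instance(r, m[1, ], "AGE_OF_DIAGNOSIS", snip, hits, "MALE")
  expect_equal(inst$age_class, assign_age_class(59, 59))
  expect_equal(inst$instance_id, "1_01")
})

test_that("the store constructor enforces instance invariants", {
  good <- make_instance("x_01", "x", 10, 20)
  bad_rel <- good; bad_rel$relationship <- "UNDETERMINED"
  expect_error(new_apk_store(bad_rel), "undetermined")
  bad_hits <- make_instance("y_01", "y", 10, 20)
  bad_hits$hits <- list(bad_hits$hits[[1]][0, ])
  expect_error(new_apk_store(bad_hits), "without phenotype")
  bad_cls <- good; bad_cls$age_class <- "AGED"
  expect_error(new_apk_store(bad_cls), "age class")
})

test_that("the wiki preset drops occurrence, evaluation and inferred", {
  st <- fixture_store()
  out <- query_store(st, wiki_preset = TRUE)
  expect_equal(nrow(out), 5)
  expect_false(any(out$relationship %in% c("AGE_OF_OCCURRENCE",
                                           "AGE_OF_EVALUATION")))
  expect_false(any(out$inferred))
})

test_that("age queries use interval intersection with a contained mode", {
  st <- fixture_store()
  out <- query_store(st, age = "ADOLESCENT")
  # ranges intersecting [12,18]: a, b, c, f
  expect_setequal(out$pmid, c("a", "b", "c", "f"))
  # brute-force oracle over the fixture
  want <- st$pmid[st$low_years <= 18 & st$high_years >= 12]
  expect_setequal(out$pmid, want)
  strict <- query_store(st, age = "ADOLESCENT", contained = TRUE)
  expect_setequal(strict$pmid, c("a", "b"))
  point <- query_store(st, age = 60)
  expect_setequal(point$pmid, c("e", "i"))
})

test_that("phenotype queries expand over the ontology hierarchy", {
  st <- fixture_store()
  ont <- pool_ontology()
  cancer <- query_store(st, ontology = ont, phenotypes = "DOID:0000002")
  expect_setequal(cancer$pmid, c("a", "b", "c", "e", "j"))
  leuk <- query_store(st, ontology = ont, phenotypes = "DOID:0000011")
  expect_true(all(leuk$pmid %in% cancer$pmid))
  root <- query_store(st, ontology = ont, phenotypes = "DOID:0000001")
  expect_equal(nrow(root), nrow(st))
  expect_error(query_store(st, ontology = ont, phenotypes = "DOID:404"),
               "DOID:404")
})

test_that("redundant hits satisfy phenotype queries only on request", {
  ont <- pool_ontology()
  # influenza instance that carries "cancer" only as a redundant hit
  st <- make_store(list(make_instance("z_01", "z", 50, 50,
                                      term = "DOID:0000021",
                                      redundant_terms = "DOID:0000002")))
  expect_equal(nrow(query_store(st, ontology = ont,
                                phenotypes = "DOID:0000002")), 0)
  expect_equal(nrow(query_store(st, ontology = ont,
                                phenotypes = "DOID:0000002",
                                include_redundant = TRUE)), 1)
})

test_that("refinement filters are conjunctive", {
  st <- fixture_store()
  ont <- pool_ontology()
  a <- query_store(st, age = c(0, 30))
  b <- query_store(st, ontology = ont, phenotypes = "DOID:0000002")
  ab <- query_store(st, ontology = ont, age = c(0, 30),
                    phenotypes = "DOID:0000002")
  expect_lte(nrow(ab), min(nrow(a), nrow(b)))
  expect_setequal(ab$pmid, intersect(a$pmid, b$pmid))
  yr <- query_store(st, year_range = c(1990, 1999))
  expect_equal(yr$pmid, "c")
  expect_equal(query_store(st, pub_type = "Review")$pmid, "j")
  expect_equal(query_store(st, curated = TRUE)$pmid, "d")
  expect_equal(query_store(st, gender = "FEMALE")$pmid, "i")
})

test_that("query results are invariant to store row order", {
  st <- fixture_store()
  ont <- pool_ontology()
  set.seed(1)
  perm <- structure(st[sample(nrow(st)), ],
                    class = c("apk_store", "data.frame"))
  q1 <- query_store(st, ontology = ont, phenotypes = "DOID:0000002")
  q2 <- query_store(perm, ontology = ont, phenotypes = "DOID:0000002")
  expect_equal(q1$instance_id, q2$instance_id)
})

test_that("results group by relationship type", {
  st <- fixture_store()
  grouped <- split_by_relationship(query_store(st))
  expect_setequal(unlist(lapply(grouped, function(g) g$pmid)), st$pmid)
  for (nm in names(grouped)) {
    expect_true(all(grouped[[nm]]$relationship == nm))
  }
})

test_that("stores round-trip losslessly and rewrite byte-identically", {
  st <- fixture_store()
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_store(st, p1)
  back <- read_store(p1)
  expect_equal(nrow(back), nrow(st))
  ord <- match(back$instance_id, st$instance_id)
  expect_equal(back$low_years, st$low_years[ord])
  expect_equal(back$snippet_text, st$snippet_text[ord])
  expect_equal(back$hits, st$hits[ord], ignore_attr = TRUE)
  write_store(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  # empty store round-trips
  p3 <- withr::local_tempfile(fileext = ".jsonl")
  write_store(new_apk_store(), p3)
  expect_equal(nrow(read_store(p3)), 0)
})

test_that("truncated or mismatched store files fail without partial load", {
  st <- fixture_store()
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_store(st, p)
  lines <- readLines(p)
  writeLines(c(lines[1], substr(lines[2], 1, 40)), p)
  expect_error(read_store(p), "corrupt")
  writeLines(sub('"schema_version":1', '"schema_version":99', lines[1]), p)
  expect_error(read_store(p), "schema")
})
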