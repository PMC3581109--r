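test_that("single-age instances put one count in one cell", {
  st <- make_store(list(make_instance("a_01", "a", 59, 59,
                                      term = "DOID:0000013")))
  m <- build_matrix(st)
  expect_equal(sum(m$counts), 1)
  expect_equal(m$counts["DOID:0000013", "59"], 1L)
  expect_equal(unname(m$instance_totals["DOID:0000013"]), 1L)
})

test_that("a multi-age range fills one cell per covered integer age", {
  st <- make_store(list(make_instance("a_01", "a", 12, 18,
                                      term = "DOID:0000011")))
  m <- build_matrix(st)
  expect_equal(sum(m$counts), 7)
  expect_equal(unname(m$counts["DOID:0000011", as.character(12:18)]),
               rep(1L, 7))
  expect_equal(unname(m$instance_totals["DOID:0000011"]), 1L)
  n <- normalize_matrix(m)
  expect_equal(unname(n$normalized["DOID:0000011", as.character(12:18)]),
               rep(1, 7))
  expect_equal(sum(n$normalized), 7)  # row sums exceed 1 for multi-age
})

test_that("fractional bounds are rounded outward", {
  st <- make_store(list(make_instance("a_01", "a", 0.5, 0.5,
                                      term = "DOID:0000011")))
  m <- build_matrix(st)
  expect_equal(unname(m$counts["DOID:0000011", c("0", "1")]), c(1L, 1L))
})

test_that("inferred ranges are excluded; empty matrices error", {
  rows <- list(make_instance("a_01", "a", 10, 12, term = "DOID:0000011"),
               make_instance("b_01", "b", 0, 30, inferred = TRUE,
                             term = "DOID:0000012"))
  m <- build_matrix(make_store(rows))
  expect_equal(m$diseases, "DOID:0000011")
  expect_error(build_matrix(make_store(rows[2])), "non-inferred")
  expect_error(build_matrix(new_apk_store()), "empty")
})

test_that("normalisation is invariant to duplicating the store", {
  fx <- generate_two_group_store(seed = 4, n_per_disease = 10)
  st <- fx$store
  dup <- st
  dup$instance_id <- paste0(dup$instance_id, "d")
  dup$pmid <- paste0(dup$pmid, "d")
  doubled <- new_apk_store(rbind(st, dup))
  n1 <- normalize_matrix(build_matrix(st))
  n2 <- normalize_matrix(build_matrix(doubled))
  expect_equal(n2$normalized, n1$normalized)
  expect_equal(n2$instance_totals, 2L * n1$instance_totals)
})

test_that("identical profiles merge at distance zero", {
  rows <- list(
    make_instance("a_01", "a", 20, 20, term = "DOID:0000011"),
    make_instance("b_01", "b", 30, 30, term = "DOID:0000011"),
    make_instance("c_01", "c", 20, 20, term = "DOID:0000012"),
    make_instance("d_01", "d", 30, 30, term = "DOID:0000012"),
    make_instance("e_01", "e", 60, 65, term = "DOID:0000013"),
    make_instance("f_01", "f", 50, 55, term = "DOID:0000013"))
  cl <- cluster_diseases(build_matrix(make_store(rows)), min_instances = 2)
  d <- as.matrix(cl$dist)
  expect_equal(d["DOID:0000011", "DOID:0000012"], 0)
  expect_equal(cl$hclust$height[1], 0)
})

test_that("pairwise distances equal a first-principles Pearson computation", {
  fx <- generate_two_group_store(seed = 12, n_per_disease = 8)
  m <- normalize_matrix(build_matrix(fx$store))
  cl <- cluster_diseases(m, min_instances = 1)
  d <- as.matrix(cl$dist)
  rows <- m$normalized[cl$diseases, , drop = FALSE]
  for (i in 1:(nrow(rows) - 1)) {
    for (j in (i + 1):nrow(rows)) {
      expect_equal(d[i, j], 1 - oracle_pearson(rows[i, ], rows[j, ]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(d >= 0 - 1e-12 & d <= 2 + 1e-12))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("too few usable rows is an error", {
  st <- make_store(list(make_instance("a_01", "a", 10, 12,
                                      term = "DOID:0000011")))
  expect_error(cluster_diseases(build_matrix(st), min_instances = 1),
               "fewer than 2")
  # zero-variance rows (flat profiles) are excluded before clustering
  rows <- list(make_instance("a_01", "a", 0, 120, term = "DOID:0000011"),
               make_instance("b_01", "b", 0, 120, term = "DOID:0000012"))
  expect_error(cluster_diseases(build_matrix(make_store(rows)),
                                min_instances = 1),
               "fewer than 2")
})

test_that("the planted two-group fixture is recovered exactly (ARI = 1)", {
  for (seed in 1:20) {
    fx <- generate_two_group_store(seed = seed)
    m <- normalize_matrix(build_matrix(fx$store))
    cl <- cluster_diseases(m, min_instances = 5)
    cut <- cut_clusters(cl, 2)
    ari <- mclust::adjustedRandIndex(cut[names(fx$partition)],
                                     fx$partition)
    expect_equal(ari, 1, info = paste("seed", seed))
  }
})

test_that("cluster age profiles average counts and locate planted peaks", {
  fx <- generate_two_group_store(seed = 3)
  m <- build_matrix(fx$store)
  g1 <- names(fx$partition)[fx$partition == 1]
  g2 <- names(fx$partition)[fx$partition == 2]
  p1 <- cluster_age_profile(m, g1)
  p2 <- cluster_age_profile(m, g2)
  expect_gte(p1$peak_age, 18)
  expect_lte(p1$peak_age, 24)
  expect_gte(p2$peak_age, 55)
  expect_lte(p2$peak_age, 65)
  single <- cluster_age_profile(m, g1[1])
  expect_equal(single$profile, m$counts[g1[1], ], ignore_attr = TRUE)
  two <- cluster_age_profile(m, g1[1:2])
  expect_equal(two$profile,
               colMeans(m$counts[g1[1:2], , drop = FALSE]),
               ignore_attr = TRUE)
})

test_that("permuting disease order changes labels only, not topology", {
  fx <- generate_two_group_store(seed = 6, n_per_disease = 12)
  m <- normalize_matrix(build_matrix(fx$store))
  cl1 <- cluster_diseases(m, min_instances = 1)
  perm <- m
  set.seed(1)
  o <- sample(length(perm$diseases))
  perm$diseases <- perm$diseases[o]
  perm$counts <- perm$counts[o, , drop = FALSE]
  perm$instance_totals <- perm$instance_totals[o]
  perm$normalized <- perm$normalized[o, , drop = FALSE]
  cl2 <- cluster_diseases(perm, min_instances = 1)
  expect_equal(sort(cl1$hclust$height), sort(cl2$hclust$height))
  c1 <- cut_clusters(cl1, 2)
  c2 <- cut_clusters(cl2, 2)
  expect_equal(mclust::adjustedRandIndex(c1[names(c2)], c2), 1)
})

test_that("dendrograms export as Newick with branch lengths", {
  fx <- generate_two_group_store(seed = 8, n_per_disease = 10)
  cl <- cluster_diseases(normalize_matrix(build_matrix(fx$store)),
                         min_instances = 1)
  nwk <- write_dendrogram(cl)
  expect_match(nwk, "^\\(.*\\);$")
  tree <- ape::read.tree(text = nwk)
  # ":" is Newick syntax; tip labels are sanitised on export
  expect_setequal(tree$tip.label, gsub(":", "-", cl$diseases))
  expect_true(all(tree$edge.length >= 0))
})
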