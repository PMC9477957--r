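cs_on <- function(labels, ...) cluster_system_on(labels, list(...))

test_that("hierarchy recognition follows nested-or-disjoint plus trivials", {
  expect_true(is_hierarchy(cs_on(c("1", "2"), "1", "2", c("1", "2"))))
  expect_false(is_hierarchy(cs_on(c("1", "2", "3"),
                                  "1", "2", "3", c("1", "2"), c("2", "3"),
                                  c("1", "2", "3"))))
  # missing trivial cluster
  expect_false(is_hierarchy(cs_on(c("1", "2"), "1", c("1", "2"))))
  # cluster systems of generated trees are hierarchies
  for (s in 1:15) {
    tr <- random_network(4 + s %% 4, 0, 1, kind = "general", seed = 30 + s)
    expect_true(is_hierarchy(cluster_system(tr)$clusters))
  }
})

test_that("P1-P3 hold for arboreal cluster systems and fail where expected", {
  for (s in 1:25) {
    h <- 1 + s %% 3
    n <- random_network(2 * (h + 1) + s %% 2, h, kind = "arboreal",
                        seed = 1200 + s)
    rep <- check_P123(cluster_system(n)$clusters)
    expect_true(rep$ok, info = s)
  }
  expect_true(check_P123(cluster_system(fixture("fig6N"))$clusters)$ok)

  # disjoint maximal clusters disconnect the intersection graph
  rep <- check_P123(cs_on(as.character(1:4), "1", "2", "3", "4",
                          c("1", "2"), c("3", "4")))
  expect_false(rep$p2)
  expect_true(rep$p1)

  # crossing clusters under one maximal cluster break P1
  rep <- check_P123(cs_on(as.character(1:3), "1", "2", "3",
                          c("1", "2"), c("2", "3"), c("1", "2", "3")))
  expect_false(rep$p1)

  # maximal intersection absent from the system breaks P3
  rep <- check_P123(cs_on(as.character(1:4), "1", "2", "3", "4",
                          c("1", "2", "3"), c("2", "3", "4")))
  expect_false(rep$p3)
})

test_that("a hierarchy rebuilds into its unique phylogenetic tree", {
  cs <- cs_on(as.character(1:3), "1", "2", "3", c("1", "2"),
              c("1", "2", "3"))
  n <- build_arboreal_network(cs)
  expect_length(roots(n), 1L)
  expect_identical(clusters_sig(n), fbnet:::clusters_key(cs))
})

test_that("rebuilding the fig6 cluster system recovers Comp(N)", {
  f6 <- fixture("fig6N")
  b <- build_arboreal_network(cluster_system(f6)$clusters)
  expect_identical(clusters_sig(b), clusters_sig(f6))
  expect_true(are_equivalent(collapse_bad_arcs(b), collapse_bad_arcs(f6)))
  expect_true(are_equivalent(collapse_bad_arcs(b),
                             collapse_bad_arcs(fixture("fig6Nprime"))))
})

test_that("reconstruction round-trips random arboreal cluster systems", {
  for (s in 1:40) {
    h <- 1 + s %% 3
    n <- random_network(2 * (h + 1) + s %% 2, h, kind = "arboreal",
                        seed = 1500 + s)
    cs <- cluster_system(n)$clusters
    b <- build_arboreal_network(cs)
    expect_identical(clusters_sig(b), fbnet:::clusters_key(cs), info = s)
    expect_true(classify(b)[["is_arboreal"]], info = s)
    expect_length(roots(b), length(maximal_clusters(cs)))
  }
})

test_that("reconstruction refuses systems violating P1-P3 or realizability", {
  expect_error(build_arboreal_network(
    cs_on(as.character(1:4), "1", "2", "3", "4", c("1", "2"), c("3", "4"))),
    "P1-P3")
  # satisfies P1-P3 but needs three distinct pairwise intersections among
  # three maximal clusters -- more hybrids than an arboreal network carries
  tri <- cs_on(as.character(1:3), "1", "2", "3",
               c("1", "2"), c("2", "3"), c("1", "3"))
  expect_true(check_P123(tri)$ok)
  expect_error(build_arboreal_network(tri), "not realizable")
  # missing trivial clusters
  expect_error(build_arboreal_network(
    cs_on(as.character(1:2), c("1", "2"))), "trivial")
})

test_that("bad arcs are hybrid-hybrid arcs and collapsing merges them", {
  expect_identical(bad_arcs(fixture("fig6N")),
                   fbnet:::normalize_arcs(rbind(c("h1", "h2"))))
  expect_identical(bad_arcs(fixture("fig6Nprime")),
                   fbnet:::normalize_arcs(rbind(c("h2", "h1"))))
  tr <- random_network(5, 0, 1, kind = "general", seed = 77)
  expect_identical(nrow(bad_arcs(tr)), 0L)
  expect_true(are_equivalent(collapse_bad_arcs(tr), tr))
  # collapse shrinks the vertex set by one per bad arc
  f6 <- fixture("fig6N")
  expect_length(collapse_bad_arcs(f6)$vertices,
                length(f6$vertices) - nrow(bad_arcs(f6)))
})

test_that("bad arcs correspond to triples of equal pairwise intersections", {
  has_triple <- function(cm) {
    m <- length(cm)
    if (m < 3L) return(FALSE)
    for (i in 1:(m - 2)) for (j in (i + 1):(m - 1)) for (k in (j + 1):m) {
      i12 <- sort(intersect(cm[[i]], cm[[j]]))
      i13 <- sort(intersect(cm[[i]], cm[[k]]))
      i23 <- sort(intersect(cm[[j]], cm[[k]]))
      if (length(i12) > 0L && identical(i12, i13) && identical(i12, i23))
        return(TRUE)
    }
    FALSE
  }
  for (s in 1:40) {
    h <- 1 + s %% 3
    n <- random_network(2 * (h + 1), h, kind = "arboreal", seed = 1900 + s)
    cm <- maximal_clusters(cluster_system(n)$clusters)
    expect_identical(nrow(bad_arcs(n)) > 0L, has_triple(cm), info = s)
  }
  expect_true(has_triple(maximal_clusters(
    cluster_system(fixture("fig6N"))$clusters)))
})

test_that("uniqueness is equivalent to the absence of bad arcs", {
  expect_false(is_uniquely_determined(fixture("fig6N")))
  tr <- random_network(5, 0, 1, kind = "general", seed = 42)
  expect_true(is_uniquely_determined(tr))
  expect_error(is_uniquely_determined(fixture("fig2")), "arboreal")
})

test_that("cluster equality coincides with collapse-equivalence", {
  f6 <- fixture("fig6N"); f6p <- fixture("fig6Nprime")
  res <- same_clusters_iff_collapse_equivalent(f6, f6p)
  expect_true(res$clusters_equal)
  expect_true(res$collapse_equivalent)

  res <- same_clusters_iff_collapse_equivalent(f6, f6)
  expect_true(res$clusters_equal && res$collapse_equivalent)

  res <- same_clusters_iff_collapse_equivalent(f6, fixture("fig5"))
  expect_false(res$clusters_equal)
  expect_false(res$collapse_equivalent)

  # property over random arboreal instances and their bad-arc swaps
  for (s in 1:25) {
    h <- 1 + s %% 3
    n <- random_network(2 * (h + 1), h, kind = "arboreal", seed = 2300 + s)
    n2 <- bad_arc_swap(n)
    if (is.null(n2)) next
    res <- same_clusters_iff_collapse_equivalent(n, n2)
    expect_identical(res$clusters_equal, res$collapse_equivalent, info = s)
  }
})
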