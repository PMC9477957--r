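test_that("validation accepts well-formed networks and the degenerate tree", {
  f2 <- fixture("fig2")
  expect_s3_class(f2, "fbnet_network")
  expect_length(roots(f2), 2L)
  expect_identical(leaves(f2), c("1", "2", "3", "4"))

  sv <- network(NULL, vertices = "x")
  expect_identical(leaves(sv), "x")
  expect_identical(roots(sv), "x")
})

test_that("each validation rule is reported with its offending element", {
  rules <- function(rep) sort(unique(vapply(rep$issues, `[[`, "", "rule")))

  rep <- validate_network(rbind(c("a", "b"), c("b", "a")))
  expect_true("cyclic" %in% rules(rep))

  rep <- validate_network(rbind(c("a", "b"), c("a", "c"),
                                c("d", "e"), c("d", "f")))
  expect_true("disconnected" %in% rules(rep))

  rep <- validate_network(rbind(c("r", "1"), c("r", "2"), c("r", "2")))
  expect_true("parallel_arc" %in% rules(rep))

  rep <- validate_network(rbind(c("r", "a"), c("r", "1"), c("a", "2")))
  expect_true("unary_tree_vertex" %in% rules(rep))

  rep <- validate_network(rbind(c("r", "a"), c("a", "1"), c("a", "2")))
  expect_true("root_outdegree" %in% rules(rep))

  # the relaxed-only indegree-3 hybrid is named in strict mode
  rep <- validate_network(fbnet:::fixture_arcs$fig9, mode = "strict")
  expect_false(rep$ok)
  msgs <- vapply(rep$issues, `[[`, "", "message")
  expect_true(any(grepl("h2", msgs) & grepl("indegree 3", msgs)))
  expect_s3_class(fixture("fig9"), "fbnet_network")
})

test_that("vertex roles, omnians and gamma match the documented facts", {
  vr7 <- vertex_roles(fixture("fig7"))
  gam <- stats::setNames(vr7$gamma, vr7$vertex)
  expect_identical(gam[["5"]], "rho2")
  expect_identical(gam[["3"]], "h1")
  expect_identical(sum(vr7$omnian), 0L)

  vr8 <- vertex_roles(fixture("fig8"))
  expect_identical(sort(vr8$vertex[vr8$omnian]), c("v", "w"))

  for (nm in c("fig2", "fig7", "fig8")) {
    vr <- vertex_roles(fixture(nm))
    for (r in roots(fixture(nm)))
      expect_identical(vr$gamma[vr$vertex == r], r)
  }
})

test_that("roles partition the vertex set and gamma lands in RH(N)", {
  for (s in 1:25) {
    n <- random_network(5, 1 + s %% 3, 1 + s %% 2, kind = "general",
                        seed = 400 + s)
    vr <- vertex_roles(n)
    expect_setequal(vr$vertex, n$vertices)
    expect_true(all(vr$role %in% c("root", "leaf", "tree", "hybrid")))
    rh <- attr(vr, "rh_set")
    expect_true(all(vr$gamma %in% rh))
    expect_identical(vr$gamma == vr$vertex, vr$vertex %in% rh)
    hyb <- hybrids(n)
    for (i in seq_len(nrow(vr))) {
      ch <- n$kids[[vr$vertex[i]]]
      expect_identical(vr$omnian[i], length(ch) > 0L && all(ch %in% hyb))
    }
  }
})

test_that("clusters are leaf sets below each vertex, nested along ancestry", {
  n <- fixture("fig2")
  cs <- cluster_system(n)
  for (x in leaves(n)) expect_identical(cs$vertex_clusters[[x]], x)
  # ancestor clusters contain descendant clusters
  for (k in seq_len(nrow(n$arcs))) {
    u <- n$arcs[k, 1L]; v <- n$arcs[k, 2L]
    expect_true(all(cs$vertex_clusters[[v]] %in% cs$vertex_clusters[[u]]))
  }
})

test_that("the fig6 networks induce identical cluster systems", {
  k1 <- fbnet:::clusters_key(cluster_system(fixture("fig6N"))$clusters)
  k2 <- fbnet:::clusters_key(cluster_system(fixture("fig6Nprime"))$clusters)
  expect_identical(k1, k2)
})

test_that("maximal clusters of arboreal networks are the root clusters", {
  for (s in 1:20) {
    n <- random_network(6 + s %% 3, 1 + s %% 3, kind = "arboreal",
                        seed = 500 + s)
    cs <- cluster_system(n)
    cm <- oracle_maximal_clusters(unname(cs$clusters))
    rootcl <- lapply(roots(n), function(r) cs$vertex_clusters[[r]])
    expect_setequal(vapply(cm, paste, character(1), collapse = ","),
                    vapply(rootcl, paste, character(1), collapse = ","))
  }
})

test_that("equivalence fixes leaf labels and ignores internal identifiers", {
  f6 <- fixture("fig6N"); f6p <- fixture("fig6Nprime")
  expect_false(are_equivalent(f6, f6p))
  expect_true(are_equivalent(collapse_bad_arcs(f6), collapse_bad_arcs(f6p)))

  # renaming internal identifiers preserves equivalence
  ren <- f6$arcs
  ren[ren == "h1"] <- "zzz"; ren[ren == "r1"] <- "qqq"
  expect_true(are_equivalent(f6, network(ren)))

  # swapping two leaf labels does not (fig6N is asymmetric in 1 vs 3)
  sw <- f6$arcs
  sw[sw == "1"] <- ".tmp"; sw[sw == "3"] <- "1"; sw[sw == ".tmp"] <- "3"
  expect_false(are_equivalent(f6, network(sw)))

  # reflexive and symmetric on fixtures
  for (nm in c("fig2", "fig5", "fig7")) {
    n <- fixture(nm)
    expect_true(are_equivalent(n, n))
  }
  expect_identical(are_equivalent(f6, f6p), are_equivalent(f6p, f6))
})

test_that("suppression collapses paths and is idempotent on hierarchies", {
  # a directed path of three vertices ending at a leaf collapses to {1}
  pathnet <- list(vertices = c("a", "b", "1"),
                  arcs = fbnet:::normalize_arcs(rbind(c("a", "b"), c("b", "1"))),
                  host_leaves = "1")
  class(pathnet) <- "fbnet_spanning_forest"
  f <- suppress(pathnet)
  expect_identical(forest_key(f), forest_key(phylo_forest(list(list("1")),
                                                          allow_single = TRUE)))

  # the fig2 embedding of {1},{2},{3,4}
  n <- fixture("fig2")
  kept <- rbind(c("rho1", "1"), c("v", "h1"), c("h1", "2"),
                c("rho2", "4"), c("rho2", "w"), c("w", "h2"), c("h2", "3"))
  f <- suppress(spanning_forest(n, kept))
  want <- phylo_forest(list(list("1"), list("2"), list(c("3", "4"))),
                       labels = c("1", "2", "3", "4"))
  expect_identical(forest_key(f), forest_key(want))

  # canonical forests are fixed points
  expect_identical(forest_key(phylo_forest(unclass(want))), forest_key(want))

  # a forest leaf outside X is rejected
  bad <- list(vertices = c("a", "b", "1"),
              arcs = fbnet:::normalize_arcs(rbind(c("a", "1"))),
              host_leaves = "1")
  class(bad) <- "fbnet_spanning_forest"
  expect_error(suppress(bad), "not a subdivision forest")
})

test_that("arboreal networks satisfy |H| = |R| - 1", {
  for (nm in c("fig5", "fig6N", "fig6Nprime")) {
    n <- fixture(nm)
    expect_true(classify(n)[["is_arboreal"]])
    expect_identical(length(hybrids(n)), length(roots(n)) - 1L)
  }
})
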