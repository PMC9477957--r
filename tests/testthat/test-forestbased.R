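test_that("the exhaustive oracle matches the documented fixture verdicts", {
  expect_null(oracle_is_forest_based(fixture("fig5")))

  cert <- oracle_is_forest_based(fixture("fig2"))
  expect_s3_class(cert, "fbnet_certificate")
  expect_true(validate_contact_certificate(fixture("fig2"), cert))

  # the cherry is forest-based with the trivial forest as base
  cherry <- network(rbind(c("r", "1"), c("r", "2")))
  cert <- oracle_is_forest_based(cherry)
  expect_identical(nrow(cert$contact_arcs), 1L)
  expect_identical(forest_key(cert$base_forest),
                   forest_key(trivial_forest(c("1", "2"))))

  expect_error(oracle_is_forest_based(network(NULL, vertices = "x")),
               "fewer than two leaves")
  expect_error(oracle_is_forest_based(fixture("fig7")), "arc budget")
})

test_that("fig2 is based on the forest {1},{2},{3,4}", {
  want <- phylo_forest(list(list("1"), list("2"), list(c("3", "4"))),
                       labels = c("1", "2", "3", "4"))
  expect_true(is_base_forest(fixture("fig2"), want))
  expect_true(is_base_forest(fixture("fig2"),
                             trivial_forest(c("1", "2", "3", "4"))))
  expect_error(is_base_forest(fixture("fig2"), trivial_forest(c("a", "b"))),
               "label set")
})

test_that("path-partition decider matches fixtures and validates certificates", {
  expect_true(is_forest_based(fixture("fig7"))$based)
  expect_false(is_forest_based(fixture("fig5"))$based)

  res <- is_forest_based(fixture("fig2"))
  expect_true(validate_contact_certificate(fixture("fig2"), res$certificate))
  # path-partition witnesses always embed the trivial forest
  expect_identical(forest_key(res$certificate$base_forest),
                   forest_key(trivial_forest(leaves(fixture("fig2")))))
  # certificate round trip: its base forest is a base forest
  expect_true(is_base_forest(fixture("fig2"), res$certificate$base_forest))
})

test_that("path-partition decider agrees with the subset oracle", {
  for (s in 1:80) {
    r <- 1 + s %% 2
    h <- max(r - 1, s %% 4)
    n <- random_network(max(2 * r, 2 + s %% 3), h, r, kind = "general",
                        seed = 7000 + s)
    if (nrow(n$arcs) > 18) next
    expect_identical(is_forest_based(n)$based,
                     !is.null(oracle_is_forest_based(n)), info = s)
  }
})

test_that("arboreal recognition matches the fixtures and yields proper forests", {
  res <- arboreal_forest_based(fixture("fig5"))
  expect_false(res$based)
  expect_true(res$witness %in% c("h1", "h2"))

  # a tree is trivially forest-based with no contact arcs
  tr <- random_network(5, 0, 1, kind = "general", seed = 3)
  res <- arboreal_forest_based(tr)
  expect_true(res$based)
  expect_identical(nrow(res$certificate$contact_arcs), 0L)

  # multi-rooted arboreal: the produced base forest has |R| components
  for (nm in c("fig6N", "fig6Nprime")) {
    n <- fixture(nm)
    res <- arboreal_forest_based(n)
    expect_true(res$based)
    expect_length(res$certificate$base_forest, length(roots(n)))
    expect_true(validate_contact_certificate(n, res$certificate))
  }
  expect_error(arboreal_forest_based(fixture("fig2")), "not arboreal")
})

test_that("arboreal recognition agrees with the general decider", {
  for (s in 1:40) {
    h <- 1 + s %% 3
    n <- random_network(2 * (h + 1), h, kind = "arboreal", seed = 7700 + s)
    a <- arboreal_forest_based(n)
    expect_identical(a$based, is_forest_based(n)$based, info = s)
    if (a$based) expect_true(validate_contact_certificate(n, a$certificate))
  }
  # fig5 is the arboreal non-example for both routes
  expect_false(is_forest_based(fixture("fig5"))$based)
})

test_that("proper recognition matches the documented fixture verdicts", {
  expect_false(is_proper_forest_based(fixture("fig7"))$proper)
  expect_true(is_proper_forest_based(fixture("fig8"))$proper)

  res <- is_proper_forest_based(fixture("fig2"))
  expect_true(res$proper)
  want <- phylo_forest(list(list(c("1", "2"), "1", "2"),
                            list(c("3", "4"), "3", "4")),
                       labels = c("1", "2", "3", "4"))
  expect_identical(forest_key(res$certificate$base_forest), forest_key(want))
  expect_error(is_proper_forest_based(fixture("fig4C")), ">= 2 roots")
})

test_that("forest-based m-networks obey the leaf bound |X| >= m", {
  n_eq <- 0L
  for (s in 1:40) {
    r <- 1 + s %% 3
    h <- max(r - 1, s %% 4)
    n <- tryCatch(random_network(2 * r + s %% 2, h, r, kind = "general",
                                 seed = 8100 + s), error = function(e) NULL)
    if (is.null(n)) next
    fb <- is_forest_based(n)$based
    m <- length(roots(n))
    if (fb) expect_gte(length(leaves(n)), m)
    if (fb && m >= 2 && length(leaves(n)) == m) {
      n_eq <- n_eq + 1L
      expect_true(is_proper_forest_based(n)$proper)
    }
  }
})

test_that("every binary tree-child network is forest-based", {
  for (s in 1:40) {
    n <- random_network(5 + s %% 2, 1 + s %% 3, 1, kind = "tree_child",
                        seed = 8800 + s)
    expect_true(is_forest_based(n)$based, info = s)
  }
})

test_that("equal-cluster arboreal networks agree on forest-basedness", {
  checked <- 0L
  for (s in 1:60) {
    h <- 1 + s %% 3
    n <- random_network(2 * (h + 1), h, kind = "arboreal", seed = 9000 + s)
    n2 <- bad_arc_swap(n)
    if (is.null(n2)) next
    checked <- checked + 1L
    expect_identical(clusters_sig(n), clusters_sig(n2), info = s)
    expect_identical(is_forest_based(n)$based, is_forest_based(n2)$based,
                     info = s)
  }
  expect_gte(checked, 10L)
})

test_that("universality holds for fig10 and the cherry, fails on 4 leaves", {
  expect_true(is_universal_forest_based(fixture("fig10")))
  expect_true(is_universal_forest_based(network(rbind(c("r", "1"),
                                                      c("r", "2")))))
  expect_false(is_universal_forest_based(fixture("fig2")))
  big <- random_network(6, 1, 1, kind = "general", seed = 5)
  expect_error(is_universal_forest_based(big), "5 leaves")
})

test_that("forbidden-configuration detection matches direct path enumeration", {
  for (p in 0:2) {
    for (q in 0:1) {
      n <- fig11_configuration(p, q)
      expect_true(has_forbidden_configuration(n, "x", "y"),
                  info = paste(p, q))
      expect_identical(has_forbidden_configuration(n, "x", "y"),
                       brute_forbidden_config(n, "x", "y"))
    }
  }
  nb <- fig11_configuration(2, 1, broken = TRUE)
  expect_false(has_forbidden_configuration(nb, "x", "y"))
  expect_identical(has_forbidden_configuration(nb, "x", "y"),
                   brute_forbidden_config(nb, "x", "y"))

  # networks whose hybrids all have tree-vertex children show nothing
  n <- fixture("fig7")   # hybrids feed leaves/tree vertices via chains
  for (x in c("1", "5")) {
    expect_identical(has_forbidden_configuration(n, x, "9"),
                     brute_forbidden_config(n, x, "9"))
  }
})
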