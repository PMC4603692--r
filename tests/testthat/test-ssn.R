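test_that("collapse_identical conserves multiplicity", {
  p <- c(z3 = "MKT", z1 = "MKT", z2 = "MKT", w = "MAG")
  reps <- collapse_identical(p)
  expect_equal(nrow(reps), 2)
  expect_setequal(reps$multiplicity, c(3, 1))
  expect_equal(reps$rep_id[reps$multiplicity == 3], "z1") # smallest id
  expect_equal(sum(reps$multiplicity), length(p))
  # all distinct: identity map
  set.seed(61)
  q <- stats::setNames(replicate(5, random_protein(30)), paste0("q", 1:5))
  rq <- collapse_identical(q)
  expect_equal(rq$multiplicity, rep(1, 5))
  expect_equal(sum(rq$multiplicity), 5)
})

test_that("networks respect the e-value threshold and strictness flag", {
  seeds <- role_seed_sequences()
  set.seed(62)
  prot <- c(
    stats::setNames(vapply(1:4, function(i)
      mutate_protein(unname(seeds["D"]), 0.8), ""), paste0("d", 1:4)),
    stats::setNames(vapply(1:4, function(i)
      mutate_protein(unname(seeds["D_bottromycin"]), 0.8), ""),
      paste0("e", 1:4)))
  g <- build_ssn(prot, threshold = 1e-54)
  ed <- igraph::as_data_frame(g, what = "edges")
  expect_true(all(ed$evalue <= 1e-54)) # no edge above threshold
  expect_false(any(ed$from == ed$to)) # no self-edges
  expect_equal(sum(igraph::V(g)$multiplicity), length(prot))
  # the two seed lineages give exactly two components
  comp <- ssn_components(g)
  expect_equal(length(unique(comp$component_id)), 2)
  d_comp <- unique(comp$component_id[grepl("^d", comp$node)])
  e_comp <- unique(comp$component_id[grepl("^e", comp$node)])
  expect_equal(length(d_comp), 1)
  expect_true(d_comp != e_comp)
  # strict flag: edges exactly at the threshold disappear
  h <- all_vs_all(prot)
  thr <- max(h$evalue[h$evalue <= 1e-54])
  g_le <- build_ssn(prot, threshold = thr, hits = h)
  g_lt <- build_ssn(prot, threshold = thr, hits = h, strict = TRUE)
  expect_lt(igraph::ecount(g_lt), igraph::ecount(g_le))
})

test_that("small components are removed, counting nodes or multiplicity", {
  set.seed(63)
  fam <- random_protein(120)
  big <- stats::setNames(vapply(1:5, function(i)
    mutate_protein(fam, 0.85), ""), paste0("big", 1:5))
  fam2 <- random_protein(120)
  small <- stats::setNames(vapply(1:4, function(i)
    mutate_protein(fam2, 0.85), ""), paste0("sm", 1:4))
  prot <- c(big, small)
  g <- build_ssn(prot, threshold = 1e-30, min_component_size = 5)
  expect_setequal(igraph::V(g)$name, names(big)) # 4-node component dropped
  # counting multiplicity: duplicate one small member so the component
  # holds 4 representatives but 5 proteins
  prot2 <- c(prot, sm1b = unname(small["sm1"]))
  g2 <- build_ssn(prot2, threshold = 1e-30, min_component_size = 5,
                  count_multiplicity = TRUE)
  expect_true(all(names(small) %in% igraph::V(g2)$name))
  g3 <- build_ssn(prot2, threshold = 1e-30, min_component_size = 5)
  expect_false(any(names(small) %in% igraph::V(g3)$name))
})

test_that("components match a union-find oracle on random graphs", {
  set.seed(64)
  for (k in 1:10) {
    n <- sample(5:15, 1)
    nodes <- paste0("n", seq_len(n))
    ne <- sample(0:12, 1)
    from <- sample(nodes, ne, replace = TRUE)
    to <- sample(nodes, ne, replace = TRUE)
    keep <- from != to
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(nodes)
    if (any(keep)) g <- igraph::add_edges(g, rbind(from[keep], to[keep]))
    got <- ssn_components(g)
    want <- oracle_components(nodes, from[keep], to[keep])
    # same partition: equal label co-membership
    got_lab <- got$component_id[match(nodes, got$node)]
    expect_equal(unname(outer(got_lab, got_lab, "==")),
                 unname(outer(unname(want), unname(want), "==")),
                 info = paste("graph", k))
  }
})

test_that("lowering the e-value threshold never merges components", {
  set.seed(65)
  base <- replicate(3, random_protein(150))
  prot <- stats::setNames(
    unlist(lapply(base, function(b)
      vapply(1:3, function(i) mutate_protein(b, 0.75), ""))),
    paste0("p", 1:9))
  h <- all_vs_all(prot)
  comp_of <- function(thr) {
    c_ <- ssn_components(build_ssn(prot, threshold = thr, hits = h))
    c_$component_id[match(names(prot), c_$node)]
  }
  loose <- comp_of(1e-5)
  tight <- comp_of(1e-60)
  # tight partition refines loose partition
  for (cc in unique(tight)) {
    members <- which(tight == cc)
    expect_equal(length(unique(loose[members])), 1)
  }
})

test_that("network export writes edge/node tables and GraphML", {
  set.seed(66)
  fam <- random_protein(100)
  prot <- stats::setNames(vapply(1:3, function(i)
    mutate_protein(fam, 0.9), ""), paste0("x", 1:3))
  g <- build_ssn(prot, threshold = 1e-20,
                 node_attrs = data.frame(id = names(prot), role = "D"))
  d <- withr::local_tempdir()
  paths <- write_ssn(g, edge_tsv = file.path(d, "e.tsv"),
                     node_tsv = file.path(d, "n.tsv"),
                     graphml = file.path(d, "g.graphml"))
  expect_true(all(file.exists(file.path(d, c("e.tsv", "n.tsv",
                                             "g.graphml")))))
  nl <- utils::read.table(file.path(d, "n.tsv"), header = TRUE, sep = "\t")
  expect_setequal(nl$name, names(prot))
  expect_true(all(nl$role == "D"))
})
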