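test_that("the curated Qo-site graph yields exactly the five proton wires", {
  g <- qo_site_graph()
  wires <- enumerate_wires(g)
  paths <- vapply(wires, function(w) paste(w$path, collapse = ">"),
                  character(1))
  expect_setequal(paths, c("QO4>H152",
                           "QO1>Y147>PRA_bL",
                           "QO1>Y147>E295>PRA_bL",
                           "QO1>Y147>Y297>PRA_bL",
                           "QO1>Y147>E295>H276>D278"))
  # 3 wires reach the heme propionate from QO1, one reaches D278, one H152
  release <- vapply(wires, function(w) w$release, character(1))
  expect_equal(sum(release == "PRA_bL"), 3L)
  expect_equal(sum(release == "D278"), 1L)
  expect_equal(sum(release == "H152"), 1L)
})

test_that("every wire satisfies the path invariants", {
  g <- qo_site_graph()
  roles <- setNames(g$nodes$role, g$nodes$name)
  for (w in enumerate_wires(g)) {
    expect_false(anyDuplicated(w$path) > 0)
    expect_equal(roles[[w$path[1]]], "donor")
    expect_equal(roles[[w$path[length(w$path)]]], "release")
    interior <- w$path[-c(1, length(w$path))]
    expect_false(any(roles[interior] == "release"))
  }
})

test_that("removing the QO1-Y147 edge leaves only the QO4 wire", {
  # Y147 is the sole initial acceptor from QO1: cutting that edge removes
  # every QO1 wire
  nodes <- utils::read.delim(system.file("extdata", "qo_nodes.tsv",
                                         package = "qowire"),
                             comment.char = "#")
  edges <- utils::read.delim(system.file("extdata", "qo_edges.tsv",
                                         package = "qowire"),
                             comment.char = "#")
  cut <- !(edges$a == "QO1" & edges$b == "Y147")
  g <- wire_graph(nodes, edges[cut, ])
  wires <- enumerate_wires(g)
  expect_length(wires, 1L)
  expect_equal(wires[[1]]$path, c("QO4", "H152"))
})

test_that("enumeration is invariant under edge input order", {
  nodes <- utils::read.delim(system.file("extdata", "qo_nodes.tsv",
                                         package = "qowire"),
                             comment.char = "#")
  edges <- utils::read.delim(system.file("extdata", "qo_edges.tsv",
                                         package = "qowire"),
                             comment.char = "#")
  set.seed(51)
  base <- vapply(enumerate_wires(wire_graph(nodes, edges)),
                 function(w) paste(w$path, collapse = ">"), character(1))
  for (i in 1:5) {
    shuf <- edges[sample.int(nrow(edges)), ]
    got <- vapply(enumerate_wires(wire_graph(nodes, shuf)),
                  function(w) paste(w$path, collapse = ">"), character(1))
    expect_identical(got, base)
  }
})

test_that("enumeration equals the brute-force sink-path oracle on random graphs", {
  set.seed(52)
  n_checked <- 0
  while (n_checked < 100) {
    rg <- random_wire_graph(10)
    if (!any(rg$nodes$role == "donor") || !any(rg$nodes$role == "release"))
      next
    n_checked <- n_checked + 1
    g <- wire_graph(rg$nodes, rg$edges)
    got <- sort(vapply(enumerate_wires(g),
                       function(w) paste(w$path, collapse = ">"),
                       character(1)))
    expect_identical(got, brute_wires(rg$nodes, rg$edges))
  }
})

test_that("single donor-release edge gives exactly one wire", {
  nodes <- data.frame(name = c("D", "R"), role = c("donor", "release"))
  edges <- data.frame(a = "D", b = "R", mechanism = "direct")
  wires <- enumerate_wires(wire_graph(nodes, edges))
  expect_length(wires, 1L)
  expect_equal(wires[[1]]$path, c("D", "R"))
})

test_that("occupancy thresholding admits 16% and rejects zero", {
  nodes <- data.frame(name = c("D", "X", "R"),
                      role = c("donor", "relay", "release"))
  edges <- data.frame(a = c("D", "X"), b = c("X", "R"),
                      mechanism = "1w", occupancy = c(0.16, 0))
  g <- wire_graph(nodes, edges, theta_min = 0.05)
  expect_equal(nrow(g$edges), 1L)       # the 16% edge survives
  expect_length(enumerate_wires(g), 0L) # path broken by the rejected edge
})

test_that("mechanisms with more than two bridging waters are rejected", {
  nodes <- data.frame(name = c("D", "R"), role = c("donor", "release"))
  edges <- data.frame(a = "D", b = "R", mechanism = c("direct", "3w"),
                      occupancy = c(NA, 0.9))
  expect_warning(g <- wire_graph(nodes, edges), "two-water")
  expect_equal(g$edges$mechanism, "direct")
  expect_error(wire_graph(data.frame(name = "D", role = "donor"),
                          data.frame(a = "D", b = "Z", mechanism = "direct")),
               "unknown node")
})

test_that("wire reports rank by bottleneck with unknowns last", {
  nodes <- data.frame(name = c("D", "X", "Y", "R"),
                      role = c("donor", "relay", "relay", "release"))
  edges <- data.frame(a = c("D", "X", "D", "Y"), b = c("X", "R", "Y", "R"),
                      mechanism = "direct",
                      occupancy = c(0.9, 0.16, 0.8, NA))
  g <- wire_graph(nodes, edges)
  wires <- enumerate_wires(g)
  rep_ <- wire_report(wires, g)
  expect_equal(nrow(rep_), length(wires))
  expect_equal(rep_$bottleneck[1], 0.16)
  expect_true(is.na(rep_$bottleneck[nrow(rep_)]))
})

test_that("enumeration agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(53)
  for (i in 1:15) {
    rg <- random_wire_graph(8)
    g <- wire_graph(rg$nodes, rg$edges)
    got <- sort(vapply(enumerate_wires(g),
                       function(w) paste(w$path, collapse = ">"),
                       character(1)))
    ig <- igraph::graph_from_data_frame(rg$edges[, c("a", "b")],
                                        directed = FALSE,
                                        vertices = rg$nodes$name)
    role <- setNames(rg$nodes$role, rg$nodes$name)
    ref <- character()
    for (d in rg$nodes$name[rg$nodes$role == "donor"])
      for (r in rg$nodes$name[rg$nodes$role == "release"]) {
        ps <- igraph::all_simple_paths(ig, from = d, to = r)
        for (p in ps) {
          nm <- igraph::V(ig)$name[p]
          interior <- nm[-c(1, length(nm))]
          if (any(role[interior] %in% c("release", "donor"))) next
          ref <- c(ref, paste(nm, collapse = ">"))
        }
      }
    expect_identical(got, sort(unique(ref)))
  }
})
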