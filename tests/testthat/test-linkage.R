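singleton_chains <- function(ids) {
  structure(lapply(ids, function(i) scaflink:::new_chain(i, "+")),
            class = "chain_list")
}

map_rows <- function(map_id, lg_id, scaffold_id, position_cM) {
  m <- data.frame(map_id = map_id, lg_id = lg_id,
                  marker_id = sprintf("m%03d", seq_along(scaffold_id)),
                  scaffold_id = scaffold_id, position_cM = position_cM,
                  stringsAsFactors = FALSE)
  m$marker_id <- paste0(m$map_id, "_", m$marker_id)
  as_linkage_map(m)
}

test_that("anchor_chains places chains by marker majority", {
  chains <- singleton_chains(c("A", "B", "C", "D"))
  m <- map_rows("male",
                c("LG3", "LG3", "LG1", "LG1", "LG1", "LG2", "LG1", "LG2"),
                c("A", "A", "B", "B", "B", "B", "C", "C"),
                c(0, 1, 0, 1, 2, 3, 0, 1))
  anch <- anchor_chains(m, chains)
  a <- anch$assignments
  expect_equal(a$lg_id[a$chain_id == "A"], "LG3")          # unanimous
  expect_equal(a$lg_id[a$chain_id == "B"], "LG1")          # 3/4 >= 2/3
  expect_equal(a$status[a$chain_id == "C"], "unplaced")    # 1/2 < 2/3
  expect_equal(a$reason[a$chain_id == "C"], "ambiguous")
  expect_equal(a$reason[a$chain_id == "D"], "no_markers")
})

test_that("anchoring aggregates markers over chain members and both maps", {
  chains <- structure(list(scaflink:::new_chain(c("s1", "s2"), c("+", "+"))),
                      class = "chain_list")
  maps <- list(map_rows("male", "LG1", "s1", 0),
               map_rows("female", c("LG1", "LG2"), c("s2", "s2"), c(1, 2)))
  anch <- anchor_chains(maps, chains)
  expect_equal(anch$assignments$lg_id, "LG1")  # 2/3 on LG1
  expect_equal(anch$assignments$n_markers, 3L)
})

test_that("constraint graph links consecutive mean-cM ranks per map", {
  chains <- singleton_chains(c("A", "B", "C", "D"))
  male <- map_rows("male", "LG1", c("A", "B", "D"), c(0, 10, 20))
  female <- map_rows("female", "LG1", c("A", "C", "D"), c(0, 12, 20))
  anch <- anchor_chains(list(male, female), chains)
  g <- build_constraint_graph(anch, list(male, female), chains)
  e <- g$lgs$LG1$edges
  expect_setequal(paste(e$from, e$to),
                  c("A B", "B D", "A C", "C D"))

  # a single placed chain yields no edges
  one <- anchor_chains(map_rows("male", "LG1", "A", 0),
                       singleton_chains("A"))
  g1 <- build_constraint_graph(one, map_rows("male", "LG1", "A", 0),
                               singleton_chains("A"))
  expect_equal(nrow(g1$lgs$LG1$edges), 0L)

  # equal means give no edge
  tie_map <- map_rows("male", "LG1", c("A", "B"), c(5, 5))
  g2 <- build_constraint_graph(anchor_chains(tie_map,
                                             singleton_chains(c("A", "B"))),
                               tie_map, singleton_chains(c("A", "B")))
  expect_equal(nrow(g2$lgs$LG1$edges), 0L)
})

make_graph <- function(nodes, edges, members = NULL) {
  if (is.null(members)) {
    members <- data.frame(chain_id = nodes$chain_id,
                          scaffold_id = nodes$chain_id,
                          orientation = "+", stringsAsFactors = FALSE)
  }
  structure(list(lgs = list(LG1 = list(nodes = nodes, edges = edges)),
                 members = members), class = "constraint_graph")
}

edge_rows <- function(from, to, support, gap, type = "map", map_id = "male") {
  n <- length(from)
  data.frame(from = from, to = to, type = rep_len(type, n),
             map_id = rep_len(map_id, n),
             support = rep_len(as.integer(support), n),
             gap = rep_len(as.numeric(gap), n),
             stringsAsFactors = FALSE)
}

test_that("resolve_cycles removes the weakest map edge on each cycle", {
  nodes <- data.frame(chain_id = c("A", "B"), mean_cM = c(0, 1),
                      n_markers = c(2L, 1L), stringsAsFactors = FALSE)
  g <- make_graph(nodes, edge_rows(c("A", "B"), c("B", "A"), c(2, 1),
                                   c(1, 1)))
  res <- resolve_cycles(g)
  expect_equal(nrow(res$removed), 1L)
  expect_equal(res$removed$from, "B")
  expect_equal(nrow(res$graph$lgs$LG1$edges), 1L)

  # acyclic input is identity
  acyc <- make_graph(nodes, edge_rows("A", "B", 2, 1))
  res2 <- resolve_cycles(acyc)
  expect_equal(nrow(res2$removed), 0L)
  expect_equal(res2$graph$lgs$LG1$edges, acyc$lgs$LG1$edges)
})

test_that("cycle removal ties cascade support, then cM gap, then endpoints", {
  nodes <- data.frame(chain_id = c("A", "B", "C"), mean_cM = c(0, 1, 2),
                      n_markers = 2L, stringsAsFactors = FALSE)
  g <- make_graph(nodes, edge_rows(c("A", "B", "C"), c("B", "C", "A"),
                                   c(3, 2, 2), c(2, 5, 1)))
  res <- resolve_cycles(g)
  expect_equal(nrow(res$removed), 1L)
  expect_equal(res$removed$from, "C")  # support 2, gap 1.0
  expect_equal(res$removed$gap, 1)
})

test_that("a cycle made only of chain-internal edges is an error", {
  nodes <- data.frame(chain_id = c("A", "B"), mean_cM = c(0, 1),
                      n_markers = 1L, stringsAsFactors = FALSE)
  g <- make_graph(nodes, edge_rows(c("A", "B"), c("B", "A"), c(1, 1),
                                   c(0, 0), type = "chain_internal"))
  expect_error(resolve_cycles(g), "chain-internal")
})

test_that("topological consensus respects edges and breaks ties by mean cM", {
  nodes <- data.frame(chain_id = c("A", "B", "C", "D"),
                      mean_cM = c(0, 10, 12, 20), n_markers = 2L,
                      stringsAsFactors = FALSE)
  g <- make_graph(nodes, edge_rows(c("A", "B", "A", "C"),
                                   c("B", "D", "C", "D"), 1, 1))
  cons <- topological_consensus(g)
  expect_equal(cons$LG1$scaffold_id, c("A", "B", "C", "D"))
  expect_equal(cons$LG1$position, 1:4)

  # two disconnected chains: smaller mean cM first
  nodes2 <- data.frame(chain_id = c("X", "Y"), mean_cM = c(4, 1),
                       n_markers = 1L, stringsAsFactors = FALSE)
  g2 <- make_graph(nodes2, edge_rows(character(), character(), integer(),
                                     numeric()))
  expect_equal(topological_consensus(g2)$LG1$scaffold_id, c("Y", "X"))

  # empty graph -> empty order
  g3 <- structure(list(lgs = list(), members = data.frame()),
                  class = "constraint_graph")
  expect_length(topological_consensus(g3), 0L)

  # an unresolved cycle is an error
  gc <- make_graph(nodes2, edge_rows(c("X", "Y"), c("Y", "X"), 1, 1))
  expect_error(topological_consensus(gc), "cycle")
})

test_that("chains flatten into the consensus with their orientations", {
  members <- data.frame(chain_id = c("AB", "AB", "C"),
                        scaffold_id = c("s1", "s2", "s3"),
                        orientation = c("+", "-", "+"),
                        stringsAsFactors = FALSE)
  nodes <- data.frame(chain_id = c("AB", "C"), mean_cM = c(0, 5),
                      n_markers = 1L, stringsAsFactors = FALSE)
  g <- make_graph(nodes, edge_rows("AB", "C", 1, 5), members)
  cons <- topological_consensus(g)
  expect_equal(cons$LG1$scaffold_id, c("s1", "s2", "s3"))
  expect_equal(cons$LG1$orientation, c("+", "-", "+"))
})

test_that("adding a marker-less chain never reorders placed chains", {
  chains <- singleton_chains(c("A", "B", "C"))
  maps <- list(map_rows("male", "LG1", c("A", "B", "C"), c(0, 5, 9)))
  base <- topological_consensus(resolve_cycles(build_constraint_graph(
    anchor_chains(maps, chains), maps, chains))$graph)

  chains2 <- singleton_chains(c("A", "B", "C", "Z"))
  with_z <- topological_consensus(resolve_cycles(build_constraint_graph(
    anchor_chains(maps, chains2), maps, chains2))$graph)
  placed <- with_z$LG1$scaffold_id[with_z$LG1$scaffold_id != "Z"]
  expect_equal(placed, base$LG1$scaffold_id)
})

test_that("lg_coverage is the placed-scaffold base fraction to 0.1 %", {
  chains <- singleton_chains(c("A", "B"))
  maps <- map_rows("male", "LG1", "A", 0)
  anch <- anchor_chains(maps, chains)
  expect_equal(lg_coverage(anch, c(A = 14, B = 86), 100), 14.0)
  expect_equal(lg_coverage(anch, c(A = 13e6, B = 87e6), 100e6), 13.0)

  none <- anchor_chains(map_rows("male", "LG1", "Q", 0), chains)
  expect_equal(lg_coverage(none, c(A = 14, B = 86), 100), 0.0)

  expect_error(lg_coverage(anch, c(B = 86), 100), "A")
})
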