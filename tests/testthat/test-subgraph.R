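# Symmetric subgraph extraction, exports, node colors, neighbor-variant scan.

test_that("BFS ball around node 1 of the example matches the oracle", {
  txt <- example_text(); idx <- example_index()
  g <- build_graph(idx, txt, k = 3, s_cp = 2)
  sub <- extract_subgraph(g, idx, 1L, 1L)
  expect_equal(sub$node_ids, c(0L, 1L, 2L, 3L, 4L))
  expect_true(all(c(1L) == sub$seed_ids))
  # edges within the ball include 1->0 and 1->4 with multiplicity 1
  key <- paste(sub$edges$from, sub$edges$to)
  expect_true("1 0" %in% key)
  expect_true("1 4" %in% key)
  expect_equal(sub$edges$mult[key == "1 0"], 1L)
  expect_equal(sub$edges$mult[key == "1 4"], 1L)
  # both endpoints of every edge are members
  expect_true(all(sub$edges$from %in% sub$node_ids))
  expect_true(all(sub$edges$to %in% sub$node_ids))
  # depth 0: seed only, no edges with external endpoints
  s0 <- extract_subgraph(g, idx, 0L, 0L)
  expect_equal(s0$node_ids, 0L)
  expect_equal(nrow(s0$edges), 0L)
  expect_error(extract_subgraph(g, idx, 99L, 1L), "unknown seed")
})

test_that("subgraph node sets equal oracle BFS balls on random texts", {
  txt <- random_pan_genome(31L, base_length = 900L, n_strains = 3L)
  idx <- build_index(txt, s_SA = 16L)
  k <- 9L
  g <- build_graph(idx, txt, k = k, s_cp = 8)
  orc <- oracle_graph(txt, k)
  map <- oracle_id_map(orc, g, idx)
  # compare on the separator-free portion: drop edges incident to end nodes
  nonend <- which(!orc$nodes$is_end)
  e <- orc$edges[orc$edges$from %in% nonend & orc$edges$to %in% nonend, ]
  ig <- igraph::graph_from_data_frame(
    e[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = nonend))
  set.seed(1)
  seeds <- sample(nonend, 4L)
  for (s in seeds) {
    for (depth in c(1L, 2L, 4L)) {
      d <- igraph::distances(ig, v = as.character(s))
      ids <- as.integer(colnames(d))[d[1L, ] <= depth]
      exp <- sort(map[ids])
      got <- extract_subgraph(g, idx, map[s], depth, dna_only = TRUE)
      expect_equal(got$node_ids, exp)
    }
  }
})

test_that("interior nodes have balanced edge multiplicities in deep balls", {
  txt <- random_pan_genome(32L, base_length = 700L)
  idx <- build_index(txt, s_SA = 16L)
  g <- build_graph(idx, txt, k = 9L, s_cp = 8)
  sub <- extract_subgraph(g, idx, 0L, 3L)
  # nodes strictly inside the ball have all their edges inside it
  interior <- sub$node_ids[sub$depth[as.character(sub$node_ids)] <
                             sub$max_depth]
  checked <- 0L
  for (v in interior) {
    if (g$nodes$is_end[v + 1L]) next
    incoming <- sum(sub$edges$mult[sub$edges$to == v])
    expect_equal(incoming, g$nodes$mult[v + 1L])
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("exports are deterministic and well-formed", {
  txt <- example_text(); idx <- example_index()
  g <- build_graph(idx, txt, k = 3, s_cp = 2)
  sub <- extract_subgraph(g, idx, 1L, 1L)
  dot1 <- export_subgraph(sub, g, idx, "dot")
  dot2 <- export_subgraph(sub, g, idx, "dot")
  expect_identical(dot1, dot2)
  expect_equal(sum(grepl("label=", strsplit(dot1, "\n")[[1]])) -
                 nrow(sub$edges), 5L)  # 5 node statements
  gfa <- export_subgraph(extract_subgraph(g, idx, 0L, 0L), g, idx, "gfa1")
  lines <- strsplit(gfa, "\n")[[1]]
  expect_equal(sum(startsWith(lines, "S\t")), 1L)
  expect_equal(lines[startsWith(lines, "S\t")], "S\t0\tGTC")
  tsv <- export_subgraph(sub, g, idx, "tsv")
  expect_true(startsWith(tsv, "from_id\tto_id\tmultiplicity"))
  expect_error(export_subgraph(sub, g, idx, "xml"))
  # empty subgraph exports to a header-only document
  e <- extract_subgraph(g, idx, 6L, 0L)
  expect_equal(export_subgraph(e, g, idx, "tsv"),
               "from_id\tto_id\tmultiplicity\n")
  # cyclic edges (leaving end nodes) are excluded unless requested
  full <- extract_subgraph(g, idx, 0:6, 3L)
  with_cyc <- export_subgraph(full, g, idx, "tsv", include_cyclic = TRUE)
  without <- export_subgraph(full, g, idx, "tsv")
  expect_gt(length(strsplit(with_cyc, "\n")[[1]]),
            length(strsplit(without, "\n")[[1]]))
  # overlap trimming drops the first k-1 label characters
  trimmed <- export_subgraph(sub, g, idx, "dot", trim_overlap = TRUE)
  expect_true(grepl("4: TGGT", trimmed))
})

test_that("node colors derive from locate", {
  txt <- example_text(); idx <- example_index()
  g <- build_graph(idx, txt, k = 3, s_cp = 2)
  expect_equal(node_colors(g, idx, 0L), c(0L, 1L))  # "GTC" in both
  expect_equal(node_colors(g, idx, 3L), 0L)         # "CTA" in strain 0
  expect_equal(node_colors(g, idx, 2L), 1L)         # "ATA" in strain 1
})

test_that("neighbor-variant scan applies all three candidate conditions", {
  # 4 strains; strains 1 and 2 carry the same marker SNP plus a shared
  # co-mutation; strain 3 is marker-free
  set.seed(99)
  base <- paste(sample(c("A", "C", "G", "T"), 200L, replace = TRUE),
                collapse = "")
  mk <- function(s, at, to) {
    substr(s, at, at) <- to
    s
  }
  s0 <- base
  s1 <- mk(mk(base, 60L, "T"), 120L, "A")   # marker + co-mutation
  s2 <- mk(mk(base, 60L, "T"), 120L, "A")   # same pair
  s3 <- base                                 # no marker
  txt <- pan_genome_text(c(s0, s1, s2, s3))
  idx <- build_index(txt, s_SA = 1L)
  k <- 11L
  g <- build_graph(idx, txt, k = k, s_cp = 8)
  # reference path: walk of strain 0 through the graph
  path <- find_node_path(g, idx, list(b = match_exact(idx, s0)$b,
                                      e = match_exact(idx, s0)$e,
                                      length = nchar(s0)))$node_path
  res <- neighbor_variant_scan(g, idx, path, marker_carriers = list(1:2),
                               max_back_steps = 30L, min_mult = 2L)
  # both variant bubbles (marker and co-mutation) qualify: carried only by
  # strains 1 and 2, multiplicity 2, coordinates assignable
  expect_equal(nrow(res), 2L)
  for (i in seq_len(nrow(res))) {
    expect_true(all(node_colors(g, idx, res$node_id[i]) %in% 1:2))
    expect_gte(g$nodes$mult[res$node_id[i] + 1L], 2L)
  }
  # a co-mutation occurring once fails the multiplicity condition
  s2b <- mk(base, 60L, "T")                  # marker only in strain 2
  txt2 <- pan_genome_text(c(s0, s1, s2b, s3))
  idx2 <- build_index(txt2, s_SA = 1L)
  g2 <- build_graph(idx2, txt2, k = k, s_cp = 8)
  path2 <- find_node_path(g2, idx2, list(b = match_exact(idx2, s0)$b,
                                         e = match_exact(idx2, s0)$e,
                                         length = nchar(s0)))$node_path
  res2 <- neighbor_variant_scan(g2, idx2, path2, marker_carriers = list(1:2),
                                max_back_steps = 30L, min_mult = 2L)
  expect_false(any(vapply(res2$node_id, function(id)
    identical(node_colors(g2, idx2, id), 1L), logical(1))))
  # a co-mutation also carried by a non-marker strain fails the color rule
  s3c <- mk(base, 120L, "A")                 # co-mutation without marker
  txt3 <- pan_genome_text(c(s0, s1, s2, s3c))
  idx3 <- build_index(txt3, s_SA = 1L)
  g3 <- build_graph(idx3, txt3, k = k, s_cp = 8)
  path3 <- find_node_path(g3, idx3, list(b = match_exact(idx3, s0)$b,
                                         e = match_exact(idx3, s0)$e,
                                         length = nchar(s0)))$node_path
  res3 <- neighbor_variant_scan(g3, idx3, path3, marker_carriers = list(1:2),
                                max_back_steps = 30L, min_mult = 2L)
  # the co-mutation bubble now has colors {1,2,3}, violating condition (ii);
  # only the marker bubble itself remains
  expect_true(all(vapply(res3$node_id, function(id)
    all(node_colors(g3, idx3, id) %in% 1:2), logical(1))))
  expect_lt(nrow(res3), nrow(res))
  expect_error(neighbor_variant_scan(g, idx, c(path[1L], path[1L]),
                                     marker_carriers = list(1:2)),
               "connected walk")
})
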