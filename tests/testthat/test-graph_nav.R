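# Elementary navigation: extreme-k-mer lookups, checkpoint-walk node
# identification, character jumps and specific-edge predecessor jumps,
# validated on the worked example and against the string-space oracle.

test_that("extreme-k-mer lookups reproduce the worked operations", {
  txt <- example_text(); idx <- example_index()
  g <- build_graph(idx, txt, k = 3, s_cp = 2)
  expect_equal(find_id_right(g, 9L), 0L)   # "GTC", rank 5
  expect_equal(find_id_right(g, 8L), 4L)   # "GGT"
  expect_equal(find_id_right(g, 0L), 5L)   # end node at the sentinel suffix
  expect_equal(find_id_left(g, 13L), 1L)   # reverse "TAT", rank 5
  expect_equal(find_id_left(g, 19L), 4L)   # reverse "TTG"
  expect_equal(find_id_left(g, 0L), 5L)
  expect_error(find_id_right(g, 20L), "out of")
  expect_error(find_id_left(g, -1L), "out of")
  # any row of the interval works
  expect_equal(find_id_right(g, 10L), 0L)
})

test_that("checkpoint walk identifies nodes from arbitrary k-mers", {
  txt <- example_text(); idx <- example_index()
  g <- build_graph(idx, txt, k = 3, s_cp = 2)
  # "TTG" has SA interval [19,20[; one LF step (LF[19] = 11) hits a
  # checkpoint bit and yields node 4 at offset 1
  expect_equal(lf(idx, 19L), 11L)
  hit <- find_id(g, idx, match_exact(idx, "TTG"))
  expect_equal(hit, list(id = 4L, offset = 1L))
  expect_equal(find_id(g, idx, match_exact(idx, "TGG")),
               list(id = 4L, offset = 2L))
  expect_equal(find_id(g, idx, match_exact(idx, "GGT")),
               list(id = 4L, offset = 3L))  # rightmost: offset = len - k
  # separator-terminated k-mers resolve to end nodes
  expect_equal(find_id(g, idx, match_exact(idx, "TC$")),
               list(id = 5L, offset = 0L))
  expect_equal(find_id(g, idx, match_exact(idx, "TC%")),
               list(id = 6L, offset = 0L))
  # a bare SA row is accepted too
  expect_equal(find_id(g, idx, 19L), list(id = 4L, offset = 1L))
})

test_that("find_id agrees with the oracle k-mer map for all s_cp", {
  for (seed in c(21L, 22L)) {
    txt <- random_pan_genome(seed, base_length = 700L)
    idx <- build_index(txt, s_SA = 16L)
    k <- 11L
    orc <- oracle_graph(txt, k)
    kmers <- ls(orc$kmap)
    kmers <- kmers[!grepl("[%$]", kmers)]          # separator-free queries
    for (s_cp in c(1L, 2L, 8L, Inf)) {
      g <- build_graph(idx, txt, k = k, s_cp = s_cp)
      map <- oracle_id_map(orc, g, idx)
      for (km in kmers) {
        exp <- get(km, envir = orc$kmap)
        hit <- find_id(g, idx, match_exact(idx, km))
        expect_equal(hit$id, map[exp[1L]])
        expect_equal(hit$offset, exp[2L])
      }
    }
  }
})

test_that("find_id rejects k-mers with interior separators", {
  txt <- example_text(); idx <- example_index()
  g <- build_graph(idx, txt, k = 3, s_cp = 2)
  r <- match_exact(idx, "C%A")
  expect_equal(range_width(r), 1L)
  expect_error(find_id(g, idx, r), "interior separation")
})

test_that("character jumps match the explicit edges of the example", {
  txt <- example_text(); idx <- example_index()
  g <- build_graph(idx, txt, k = 3, s_cp = 2)
  expect_equal(get_pred_id_with_char(g, idx, 1L, "A"), 2L)  # "ATAT"
  expect_equal(get_pred_id_with_char(g, idx, 1L, "C"), 3L)  # "CTAT"
  expect_true(is.na(get_pred_id_with_char(g, idx, 1L, "G")))
  expect_equal(get_succ_id_with_char(g, idx, 3L, "T"), 1L)
  expect_equal(get_succ_id_with_char(g, idx, 1L, "C"), 0L)  # "TGTC"
  expect_true(is.na(get_succ_id_with_char(g, idx, 1L, "A")))
  # cyclic edges through separators are discoverable
  expect_equal(get_succ_id_with_char(g, idx, 5L, "A"), 3L)  # "$CTA"
  expect_equal(get_pred_id_with_char(g, idx, 3L, "$"), 5L)
  expect_equal(get_succ_id_with_char(g, idx, 6L, "A"), 2L)  # "%ATA"
  expect_equal(get_succ_id_with_char(g, idx, 0L, "$"), 5L)
  expect_error(get_pred_id_with_char(g, idx, 9L, "A"))
})

test_that("character jumps mirror (k+1)-mer existence on random texts", {
  txt <- random_pan_genome(23L, base_length = 600L)
  idx <- build_index(txt, s_SA = 16L)
  k <- 7L
  g <- build_graph(idx, txt, k = k, s_cp = 8)
  body <- txt$T
  for (id in seq_len(g$n_nodes) - 1L) {
    if (g$nodes$is_end[id + 1L]) next
    om <- node_substring(g, idx, id)
    for (ch in c("A", "C", "G", "T")) {
      kp1 <- paste0(ch, substr(om, 1L, k))
      starts <- seq_len(nchar(body) - k)
      present <- any(substring(body, starts, starts + k) == kp1)
      got <- get_pred_id_with_char(g, idx, id, ch)
      expect_equal(!is.na(got), present)
      if (present) {
        # the predecessor's substring must end with the (k+1)-mer's prefix k
        pom <- node_substring(g, idx, got)
        expect_equal(substr(pom, nchar(pom) - k + 1L, nchar(pom)),
                     substr(kp1, 1L, k))
      }
    }
  }
})

test_that("specific-edge jumps reproduce the derived examples", {
  txt <- example_text(); idx <- example_index()
  g <- build_graph(idx, txt, k = 3, s_cp = 2)
  expect_equal(jump_pred_via_edge(g, idx, 0L, 0L)$id, 4L)  # LF(9)=8
  expect_equal(jump_pred_via_edge(g, idx, 0L, 1L)$id, 1L)  # LF(10)=17
  expect_equal(jump_pred_via_edge(g, idx, 5L, 0L)$id, 0L)  # LF(14)=9
  expect_error(jump_pred_via_edge(g, idx, 0L, 2L), "edge_offset")
})

test_that("edge enumeration over edge offsets equals the oracle multiset", {
  txt <- random_pan_genome(24L, base_length = 800L, n_strains = 3L)
  idx <- build_index(txt, s_SA = 16L)
  k <- 9L
  g <- build_graph(idx, txt, k = k, s_cp = 8)
  orc <- oracle_graph(txt, k)
  map <- oracle_id_map(orc, g, idx)
  impl <- lapply(seq_len(g$n_nodes) - 1L, function(v)
    sort(vapply(seq_len(g$nodes$mult[v + 1L]) - 1L, function(eo)
      jump_pred_via_edge(g, idx, v, eo)$id, integer(1))))
  for (i in seq_len(nrow(orc$nodes))) {
    v <- map[i]
    exp <- sort(map[rep(orc$edges$from[orc$edges$to == i],
                        orc$edges$mult[orc$edges$to == i])])
    expect_equal(impl[[v + 1L]], exp)
  }
  # the returned edge offset lies in the predecessor's incoming range and
  # distinct occurrences map to distinct (pred, offset) slots
  slots <- character(0)
  for (v in seq_len(g$n_nodes) - 1L) {
    for (eo in seq_len(g$nodes$mult[v + 1L]) - 1L) {
      j <- jump_pred_via_edge(g, idx, v, eo)
      expect_gte(j$edge_offset, 0L)
      expect_lt(j$edge_offset, g$nodes$mult[j$id + 1L])
      slots <- c(slots, paste(j$id, j$edge_offset))
    }
  }
  expect_false(anyDuplicated(slots) > 0L)
})
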