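# Search schemes: construction, validation, file IO, pattern partitioning,
# and lossless approximate matching against the brute-force scanner.

test_that("pigeonhole schemes have the documented searches and are valid", {
  s2 <- pigeonhole_scheme(2)
  got <- lapply(s2$searches, function(s) paste(s$pi, collapse = ""))
  expect_setequal(unlist(got), c("012", "210", "102"))
  for (s in s2$searches) {
    expect_equal(s$L, rep(0L, 3L))
    expect_equal(s$U[1L], 0L)
    expect_equal(max(s$U), 2L)
  }
  s0 <- pigeonhole_scheme(0)
  expect_equal(length(s0$searches), 1L)
  expect_equal(s0$searches[[1L]], list(pi = 0L, L = 0L, U = 0L))
  s1 <- pigeonhole_scheme(1)
  expect_equal(length(s1$searches), 2L)
  expect_equal(s1$p, 2L)
  for (K in 0:4) {
    v <- validate_scheme(pigeonhole_scheme(K))
    expect_true(v$valid)
    expect_equal(nrow(v$uncovered), 0L)
  }
  expect_error(pigeonhole_scheme(5), "between 0 and 4")
})

test_that("the Kucherov K=2 scheme matches its published triplets", {
  sch <- kucherov_k2_scheme()
  expect_equal(sch$searches[[1L]],
               list(pi = 0:2, L = c(0L, 1L, 2L), U = c(0L, 2L, 2L)))
  expect_equal(sch$searches[[2L]],
               list(pi = c(2L, 1L, 0L), L = rep(0L, 3L), U = c(0L, 1L, 2L)))
  expect_equal(sch$searches[[3L]],
               list(pi = c(1L, 0L, 2L), L = c(0L, 0L, 1L), U = c(0L, 1L, 2L)))
  expect_true(validate_scheme(sch)$valid)
  # the third search covers exactly these exact-weight-2 distributions
  # plus [1,0,0] at lower weight
  cov <- covered_distributions(sch$searches[[3L]], 3L, 2L, exact_sum = FALSE)
  cov <- cov[rowSums(cov) >= 1L, , drop = FALSE]
  expect_equal(cov[order(cov[, 1L], cov[, 2L], cov[, 3L]), , drop = FALSE],
               rbind(c(0L, 0L, 1L), c(0L, 0L, 2L), c(1L, 0L, 0L),
                     c(1L, 0L, 1L)))
  # removing any single search breaks coverage
  for (drop in 1:3) {
    partial <- panbdg:::new_scheme(sch$searches[-drop], 2L)
    expect_false(validate_scheme(partial)$valid)
  }
})

test_that("validate_scheme reports uncovered distributions", {
  lone <- panbdg:::new_scheme(list(
    panbdg:::new_search(0:2, c(0L, 1L, 2L), c(0L, 2L, 2L))), 2L)
  v <- validate_scheme(lone)
  expect_false(v$valid)
  expect_true(any(apply(v$uncovered, 1L, identical, y = c(2L, 0L, 0L))))
})

test_that("scheme files round-trip and malformed files are rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 2", "012 000 022", "210 000 022", "102 000 022"), path)
  sch <- load_scheme(path)
  expect_equal(sch$K, 2L)
  expect_equal(length(sch$searches), 3L)
  expect_true(validate_scheme(sch)$valid)
  bad1 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 2", "021 000 022"), bad1)
  expect_error(load_scheme(bad1), "connectivity")
  bad1b <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 2", "020 000 022"), bad1b)
  expect_error(load_scheme(bad1b), "permutation")
  bad2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 2", "012 012 022", "210 000 012"), bad2)
  expect_error(load_scheme(bad2), "does not cover")
  bad3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 2", "012 000"), bad3)
  expect_error(load_scheme(bad3), "malformed")
})

test_that("pattern partitioning is uniform with the remainder leftmost", {
  p <- partition_pattern(strrep("A", 101L), 3L)
  expect_equal(nchar(p), c(34L, 34L, 33L))
  expect_equal(partition_pattern("ABCDEFGHI", 3L), c("ABC", "DEF", "GHI"))
  expect_equal(paste(partition_pattern("ACGTACG", 3L), collapse = ""),
               "ACGTACG")
  expect_error(partition_pattern("AC", 3L), "cannot be cut")
})

test_that("approximate matching reproduces the worked-example hits", {
  idx <- example_index()
  occ0 <- approximate_match(idx, "ATGTT", 0L)
  expect_equal(nrow(occ0), 1L)
  loc <- locate(idx, bd_range(occ0$b, occ0$e, occ0$b_r, occ0$e_r), 5L)
  expect_equal(loc$global_pos, 10L)
  expect_equal(occ0$ed, 0L)
  occ1 <- approximate_match(idx, "ATGTC", 1L)
  tx <- do.call(rbind, lapply(seq_len(nrow(occ1)), function(i)
    to_text_occurrences(idx, idx$text, occ1[i, ], query_id = "q")))
  best <- filter_redundant(tx)
  best <- best[order(best$seq_index, best$start), ]
  glob <- best$start + idx$text$seq_starts[best$seq_index + 1L]
  expect_equal(glob, c(2L, 10L))   # exact hit and the 1-error hit
  expect_equal(best$ed, c(0L, 1L))
  expect_equal(nrow(approximate_match(idx, "AAAAA", 1L)), 0L)
  expect_error(approximate_match(idx, "ATGTC", 5L), "unsupported")
})

test_that("K = 0 reduces to exact matching", {
  txt <- random_pan_genome(41L, base_length = 800L)
  idx <- build_index(txt, s_SA = 16L)
  set.seed(5)
  for (rep in 1:10) {
    from <- sample(500L, 1L)
    P <- substr(txt$T, from, from + 19L)
    if (grepl("[%$]", P)) next
    r <- match_exact(idx, P)
    occ <- approximate_match(idx, P, 0L)
    expect_equal(nrow(occ), 1L)
    expect_equal(occ$b, r$b)
    expect_equal(occ$e, r$e)
    expect_equal(occ$ed, 0L)
  }
})

test_that("search schemes are lossless against the brute-force scanner", {
  n_bad <- 0L
  for (seed in c(51L, 52L, 53L)) {
    cfg <- synth_config(base_length = 1500L, n_strains = 3L, seed = seed,
                        read_length = 60L, n_reads = 10L,
                        planted_errors = 3L)
    pg <- generate_pan_genome(cfg)
    idx <- build_index(pg$text, s_SA = 16L)
    rd <- sample_reads(pg$text, cfg)
    for (K in 0:4) {
      schemes <- list(pigeonhole_scheme(K))
      if (K == 2L) schemes <- c(schemes, list(kucherov_k2_scheme()))
      res <- lapply(schemes, function(sch) {
        do.call(rbind, lapply(rd$reads, function(P)
          expand_text_occs(idx, approximate_match(idx, P, K, sch))))
      })
      exp <- do.call(rbind, lapply(rd$reads, function(P)
        brute_force_occurrences(pg$text, P, K)))
      rownames(exp) <- NULL
      for (r in res) {
        rownames(r) <- NULL
        if (!isTRUE(all.equal(r, exp))) n_bad <- n_bad + 1L
      }
    }
  }
  expect_equal(n_bad, 0L)
})

test_that("a loaded scheme yields the same occurrences as the built-in", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 2", "012 012 022", "210 000 012", "102 001 012"), path)
  sch <- load_scheme(path)
  txt <- random_pan_genome(54L, base_length = 1000L)
  idx <- build_index(txt, s_SA = 16L)
  set.seed(9)
  for (rep in 1:5) {
    from <- sample(800L, 1L)
    P <- substr(txt$T, from, from + 49L)
    if (grepl("[%$]", P)) next
    expect_equal(approximate_match(idx, P, 2L, sch),
                 approximate_match(idx, P, 2L, pigeonhole_scheme(2L)))
  }
})
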