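# Independent explicit-graph oracle.  Works purely in string space (direct
# k-mer enumeration, hash maps and igraph for distances) and never touches
# the FM-index machinery, so it can arbitrate graph structure, navigation
# and BFS results.

oracle_graph <- function(text, k) {
  T <- text$T
  n <- nchar(T)
  starts <- seq_len(n - k + 1L)                    # 1-based window starts
  win <- substring(T, starts, starts + k - 1L)
  valid <- !grepl("[%$]", substring(win, 1L, k - 1L))
  pos0 <- starts[valid] - 1L                       # 0-based
  km <- win[valid]
  kmers <- unique(km)
  barrier <- grepl("[%$]$", kmers)
  occ_of <- split(pos0, factor(km, levels = kmers))

  # distinct successor/predecessor k-mer sets from position adjacency
  posset <- rep(FALSE, n); posset[pos0 + 1L] <- TRUE
  p_ok <- pos0[pos0 + 1L <= n - k & posset[pos0 + 2L]]
  kf <- substring(T, p_ok + 1L, p_ok + k)
  kt <- substring(T, p_ok + 2L, p_ok + k + 1L)
  paircnt <- table(paste(kf, kt))
  kcnt <- lengths(occ_of)
  names(kcnt) <- kmers
  # u -> v is a merge edge when every occurrence of u is followed by v and
  # every occurrence of v is preceded by u, neither being a separator k-mer
  merge_next <- function(u) {
    su <- unique(kt[kf == u])
    for (v in su) {
      cnt <- paircnt[[paste(u, v)]]
      if (cnt == kcnt[[u]] && cnt == kcnt[[v]] &&
          !grepl("[%$]$", u) && !grepl("[%$]$", v))
        return(v)
    }
    NA_character_
  }
  merge_prev_exists <- function(x) {
    if (grepl("[%$]$", x)) return(FALSE)
    pr <- unique(kf[kt == x])
    for (w in pr) {
      cnt <- paircnt[[paste(w, x)]]
      if (cnt == kcnt[[w]] && cnt == kcnt[[x]] && !grepl("[%$]$", w))
        return(TRUE)
    }
    FALSE
  }
  omegas <- character(0)
  omega_kmers <- list()
  seen <- character(0)
  for (x in kmers[!barrier]) {
    if (x %in% seen || merge_prev_exists(x)) next
    chain <- x
    cur <- x
    repeat {
      nx <- merge_next(cur)
      if (is.na(nx) || nx %in% chain) break
      chain <- c(chain, nx)
      cur <- nx
    }
    seen <- c(seen, chain)
    omegas <- c(omegas, paste0(chain[1L],
                               paste(substring(chain[-1L], k, k),
                                     collapse = "")))
    omega_kmers[[length(omega_kmers) + 1L]] <- chain
  }
  # end nodes: one per separator position, omega = the separator k-mer
  seps <- which(strsplit(T, "")[[1L]] %in% c("%", "$")) - 1L
  end_om <- substring(T, seps - k + 2L, seps + 1L)

  n_ne <- length(omegas)
  S <- length(seps)
  nodes <- data.frame(
    omega = c(omegas, end_om),
    len = nchar(c(omegas, end_om)),
    is_end = c(rep(FALSE, n_ne), rep(TRUE, S)),
    stringsAsFactors = FALSE)
  nodes$mult <- NA_integer_
  node_start <- vector("list", nrow(nodes))
  for (i in seq_len(n_ne)) {
    p <- occ_of[[omega_kmers[[i]][1L]]]
    node_start[[i]] <- sort(p)
    nodes$mult[i] <- length(p)
  }
  for (j in seq_len(S)) {
    node_start[[n_ne + j]] <- seps[j] - k + 1L
    nodes$mult[n_ne + j] <- 1L
  }
  nodes$start <- node_start

  # k-mer -> (node index, offset) map
  kmap <- new.env(parent = emptyenv())
  for (i in seq_len(n_ne)) {
    ch <- omega_kmers[[i]]
    for (off in seq_along(ch) - 1L)
      assign(ch[off + 1L], c(i, off), envir = kmap)
  }
  for (j in seq_len(S)) assign(end_om[j], c(n_ne + j, 0L), envir = kmap)

  # edge multiset: node boundaries plus one cyclic edge per end node
  node_of_pos <- new.env(parent = emptyenv())      # occurrence start -> node
  for (i in seq_len(nrow(nodes)))
    for (p in nodes$start[[i]])
      assign(as.character(p), i, envir = node_of_pos)
  ef <- et <- integer(0)
  for (i in seq_len(nrow(nodes))) {
    len <- nodes$len[i]
    for (p in nodes$start[[i]]) {
      if (nodes$is_end[i]) {
        q <- (p + len) %% n                        # cyclic successor
      } else {
        q <- p + len - k + 1L                      # window after rightmost
        if (q > n - k || !posset[q + 1L]) next
        nxt <- substring(T, q + 1L, q + k)
        if (!grepl("[%$]$", nxt)) {
          hit <- get(nxt, envir = kmap)
          if (hit[2L] != 0L) next                  # internal, not a boundary
        }
      }
      v <- get(as.character(q), envir = node_of_pos)
      ef <- c(ef, i); et <- c(et, v)
    }
  }
  edges <- stats::aggregate(list(mult = rep(1L, length(ef))),
                            by = list(from = ef, to = et), FUN = sum)
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges, kmap = kmap, n_nonend = n_ne, S = S)
}

# match oracle node indices (1-based) to implementation ids (0-based) by
# (omega, start positions); end nodes disambiguated by start position
oracle_id_map <- function(orc, graph, index) {
  impl_key <- vapply(seq_len(graph$n_nodes) - 1L, function(id) {
    nd <- graph$nodes[id + 1L, ]
    if (nd$is_end) return(paste0("E", sa_value_pub(index, nd$left_kmer)))
    loc <- locate(index, bd_range(nd$left_kmer, nd$left_kmer + nd$mult,
                                  0L, nd$mult), nd$len)
    paste0(node_substring(graph, index, id), "@", min(loc$global_pos))
  }, character(1))
  orc_key <- vapply(seq_len(nrow(orc$nodes)), function(i) {
    if (orc$nodes$is_end[i]) paste0("E", orc$nodes$start[[i]][1L])
    else paste0(orc$nodes$omega[i], "@", min(orc$nodes$start[[i]]))
  }, character(1))
  m <- match(orc_key, impl_key)
  stopifnot(!anyNA(m))
  m - 1L                                           # oracle index -> impl id
}

sa_value_pub <- function(index, row) {
  loc <- locate(index, bd_range(row, row + 1L, 0L, 1L), 0L)
  loc$global_pos[1L]
}

# undirected BFS ball over the oracle edges
oracle_ball <- function(orc, seeds, depth) {
  g <- igraph::graph_from_data_frame(
    orc$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(orc$nodes))))
  d <- igraph::distances(g, v = as.character(seeds))
  cols <- as.integer(colnames(d))
  sort(cols[apply(d, 2L, min) <= depth])
}

# all (node, offset) positions of O inside node substrings (overlap-aware)
oracle_short_positions <- function(orc, O, k) {
  l <- nchar(O)
  ids <- offs <- integer(0)
  for (i in seq_len(nrow(orc$nodes))) {
    om <- orc$nodes$omega[i]
    if (nchar(om) < l) next
    for (st in 0:(nchar(om) - l)) {
      if (substr(om, st + 1L, st + l) == O) {
        ids <- c(ids, i); offs <- c(offs, st)
      }
    }
  }
  unique(data.frame(id = ids, offset = offs))
}

# expand FM occurrences to (global start, length, ed) rows for comparison
# with the brute-force scanner
expand_text_occs <- function(idx, occs) {
  if (nrow(occs) == 0L)
    return(data.frame(start = integer(0), length = integer(0),
                      ed = integer(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(occs)), function(i) {
    o <- occs[i, ]
    loc <- locate(idx, bd_range(o$b, o$e, o$b_r, o$e_r), o$length)
    data.frame(start = loc$global_pos, length = o$length, ed = o$ed)
  }))
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_pan_genome <- function(seed, base_length = 1500L, n_strains = 3L,
                              sub = 0.01, ind = 0.002) {
  generate_pan_genome(synth_config(
    base_length = base_length, n_strains = n_strains,
    substitution_rate = sub, indel_rate = ind, seed = seed))$text
}
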