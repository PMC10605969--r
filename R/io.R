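# FASTA input (with seeded N replacement) and the on-disk index format:
# a versioned directory of flat binary arrays plus a JSON metadata file.

#' Read a multi-FASTA pan-genome
#'
#' Record order defines sequence indices 0..S-1; headers become sequence
#' names.  Occurrences of 'N' are replaced by a seeded pseudo-random
#' nucleotide (the seed is recorded by [cmd_build] in the index metadata);
#' any other ambiguity code is rejected.
#'
#' @param path FASTA file.
#' @param n_seed Seed for the N replacement (default 42).
#' @return A [pan_genome_text].
#' @export
read_pan_genome <- function(path, n_seed = 42L) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  with_seed(n_seed, {
    seqs <- vapply(seqs, function(s) {
      idx <- gregexpr("N", s, fixed = TRUE)[[1L]]
      if (idx[1L] == -1L) return(s)
      ch <- strsplit(s, "")[[1L]]
      ch[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  nm <- sub("\\s.*$", "", names(ss))
  pan_genome_text(seqs, nm)
}

#' Write sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

INDEX_FORMAT_VERSION <- 1L

write_bin_int <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(x), con, size = 8L)
  writeBin(as.integer(x), con, size = 4L, endian = "little")
}

read_bin_int <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  len <- readBin(con, "integer", n = 1L, size = 8L)
  readBin(con, "integer", n = len, size = 4L, endian = "little")
}

#' Save an index (and optionally its graph) to a directory
#'
#' Writes each component as a flat little-endian int32 array plus a JSON
#' metadata file (`format version`, `k`, `s_SA`, `s_cp`, N-replacement
#' seed, sequence names/starts).  [load_index] round-trips bit-exactly.
#'
#' @param index A [build_index] result.
#' @param dir Target directory (created if needed).
#' @param graph Optional [build_graph] result.
#' @param n_seed The N-replacement seed to record.
#' @return `dir`, invisibly.
#' @export
save_index <- function(index, dir, graph = NULL, n_seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  text <- index$text
  meta <- list(format_version = INDEX_FORMAT_VERSION,
               n = index$n, S = text$S, s_SA = index$s_SA,
               n_seed = n_seed,
               seq_names = text$seq_names,
               seq_starts = text$seq_starts,
               seq_lens = text$seq_lens,
               has_graph = !is.null(graph))
  if (!is.null(graph)) {
    meta$k <- graph$k
    meta$s_cp <- if (is.finite(graph$s_cp)) graph$s_cp else "Inf"
    meta$n_nodes <- graph$n_nodes
  }
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "meta.json"))
  writeLines(text$T, file.path(dir, "text.txt"))
  comp <- list(bwt = index$bwt, bwt_r = index$bwt_r,
               sa_samp = index$sa_samp, sa_r_samp = index$sa_r_samp,
               sa_mark = as.integer(index$sa_mark),
               sa_r_mark = as.integer(index$sa_r_mark))
  if (!is.null(graph)) {
    comp <- c(comp, list(
      g_len = graph$nodes$len, g_mult = graph$nodes$mult,
      g_left = graph$nodes$left_kmer, g_rkr = graph$nodes$right_kmer_r,
      g_isend = as.integer(graph$nodes$is_end),
      B = graph$B, B_r = graph$B_r,
      idmap_id = graph$idmap$id, idmap_off = graph$idmap$offset,
      idmap_r = graph$idmap_r,
      end_sep = graph$end_sep, end_start = graph$end_start))
  }
  for (nm in names(comp))
    write_bin_int(comp[[nm]], file.path(dir, paste0(nm, ".bin")))
  invisible(dir)
}

#' Load an index directory written by [save_index]
#'
#' @param dir Index directory.
#' @return List with `index` (class `bd_fm_index`), `graph` (`ccdbg` or
#'   `NULL`) and `meta`.
#' @export
load_index <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  if (meta$format_version != INDEX_FORMAT_VERSION)
    stop("unsupported index format version ", meta$format_version)
  T <- readLines(file.path(dir, "text.txt"))[1L]
  text <- as_pan_genome_text(T, meta$seq_names)
  rd <- function(nm) read_bin_int(file.path(dir, paste0(nm, ".bin")))
  n <- meta$n
  bwt <- rd("bwt"); bwt_r <- rd("bwt_r")
  occ <- matrix(0L, n + 1L, 6L); occ_r <- matrix(0L, n + 1L, 6L)
  for (c in 0:5) {
    occ[, c + 1L] <- c(0L, cumsum(bwt == c))
    occ_r[, c + 1L] <- c(0L, cumsum(bwt_r == c))
  }
  C <- c(0L, cumsum(tabulate(bwt + 1L, nbins = 6L)))
  sa_mark <- as.logical(rd("sa_mark")); sa_r_mark <- as.logical(rd("sa_r_mark"))
  index <- structure(
    list(text = text, n = n, s_SA = meta$s_SA, C = C,
         bwt = bwt, occ = occ,
         sa_mark = sa_mark, sa_samp = rd("sa_samp"),
         sa_mark_rank = cumsum(sa_mark),
         bwt_r = bwt_r, occ_r = occ_r,
         sa_r_mark = sa_r_mark, sa_r_samp = rd("sa_r_samp"),
         sa_r_mark_rank = cumsum(sa_r_mark),
         pos_list = lapply(0:5, function(c) which(bwt == c) - 1L)),
    class = "bd_fm_index")
  graph <- NULL
  if (isTRUE(meta$has_graph)) {
    B <- rd("B"); B_r <- rd("B_r")
    graph <- structure(
      list(nodes = data.frame(len = rd("g_len"), mult = rd("g_mult"),
                              left_kmer = rd("g_left"),
                              right_kmer_r = rd("g_rkr"),
                              is_end = as.logical(rd("g_isend"))),
           n_nodes = meta$n_nodes, k = meta$k,
           s_cp = if (identical(meta$s_cp, "Inf")) Inf else meta$s_cp,
           S = meta$S, n = n,
           B = B, B_rank0 = c(0L, cumsum(B)), B_sel = which(B == 1L) - 1L,
           idmap = data.frame(id = rd("idmap_id"), offset = rd("idmap_off")),
           B_r = B_r, B_r_rank0 = c(0L, cumsum(B_r)),
           idmap_r = rd("idmap_r"),
           end_sep = rd("end_sep"), end_start = rd("end_start")),
      class = "ccdbg")
  }
  list(index = index, graph = graph, meta = meta)
}
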