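# Seeded generator of toy pan-genomes and reads.  Strain 0 is a uniform
# random DNA sequence; further strains are derived from it by seeded
# substitutions and short indels, so the ground truth (every applied
# mutation, every read's origin) is known exactly.

#' Configuration for the synthetic pan-genome generator
#'
#' @param base_length Length of the base strain (default 6000 bp).
#' @param n_strains Number of strains including the base (default 3).
#' @param substitution_rate Per-site substitution probability for derived
#'   strains (default 0.005, the order of divergence between closely
#'   related bacterial strains).
#' @param indel_rate Per-site indel probability (default 0.001).
#' @param max_indel_len Maximum indel length (default 3).
#' @param read_length Length of sampled reads (default 80).
#' @param n_reads Number of reads to sample (default 100).
#' @param planted_errors Maximum number of edits planted per read (each read
#'   receives 0..planted_errors edits; default 2).
#' @param margin Mutations avoid the first/last `margin` bases of each
#'   strain so end-node bookkeeping cannot touch truth loci (default 25).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(base_length = 6000L, n_strains = 3L,
                         substitution_rate = 0.005, indel_rate = 0.001,
                         max_indel_len = 3L, read_length = 80L,
                         n_reads = 100L, planted_errors = 2L,
                         margin = 25L, seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            base_length > 2L * margin, n_strains >= 1L,
            read_length >= 1L, planted_errors >= 0L)
  structure(list(base_length = as.integer(base_length),
                 n_strains = as.integer(n_strains),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 max_indel_len = as.integer(max_indel_len),
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 planted_errors = as.integer(planted_errors),
                 margin = as.integer(margin),
                 seed = as.integer(seed)),
            class = "synth_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Generate a synthetic pan-genome with known truth
#'
#' @param cfg A [synth_config].
#' @return List with `text` (a [pan_genome_text]), `truth` (data.frame of
#'   applied mutations: `strain`, `type` in sub/ins/del, `pos` — 0-based
#'   base-strain coordinate — `ref`, `alt`) and `cfg`.
#' @export
generate_pan_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    base <- random_dna(cfg$base_length)
    seqs <- character(cfg$n_strains)
    seqs[1L] <- base
    tr_strain <- tr_type <- tr_ref <- tr_alt <- character(0)
    tr_pos <- integer(0)
    interior <- seq.int(cfg$margin, cfg$base_length - cfg$margin - 1L)
    for (s in seq_len(cfg$n_strains - 1L)) {
      chars <- strsplit(base, "")[[1L]]
      nsub <- stats::rbinom(1L, length(interior), cfg$substitution_rate)
      subs <- sort(sample(interior, nsub))
      for (p in subs) {
        ref <- chars[p + 1L]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        chars[p + 1L] <- alt
        tr_strain <- c(tr_strain, paste0("strain_", s))
        tr_type <- c(tr_type, "sub"); tr_pos <- c(tr_pos, p)
        tr_ref <- c(tr_ref, ref); tr_alt <- c(tr_alt, alt)
      }
      nind <- stats::rbinom(1L, length(interior), cfg$indel_rate)
      inds <- sort(sample(setdiff(interior, subs), nind), decreasing = TRUE)
      for (p in inds) {
        ilen <- sample(cfg$max_indel_len, 1L)
        if (stats::runif(1L) < 0.5) {
          ins <- random_dna(ilen)
          chars <- append(chars, strsplit(ins, "")[[1L]], after = p + 1L)
          tr_type <- c(tr_type, "ins"); tr_ref <- c(tr_ref, "")
          tr_alt <- c(tr_alt, ins)
        } else {
          ilen <- min(ilen, cfg$base_length - cfg$margin - p)
          del <- paste(chars[(p + 1L):(p + ilen)], collapse = "")
          chars <- chars[-((p + 1L):(p + ilen))]
          tr_type <- c(tr_type, "del"); tr_ref <- c(tr_ref, del)
          tr_alt <- c(tr_alt, "")
        }
        tr_strain <- c(tr_strain, paste0("strain_", s))
        tr_pos <- c(tr_pos, p)
      }
      seqs[s + 1L] <- paste(chars, collapse = "")
    }
    list(text = pan_genome_text(seqs, paste0("strain_",
                                             seq_len(cfg$n_strains) - 1L)),
         truth = data.frame(strain = tr_strain, type = tr_type, pos = tr_pos,
                            ref = tr_ref, alt = tr_alt),
         cfg = cfg)
  })
}

plant_edits <- function(read, n_edits) {
  for (i in seq_len(n_edits)) {
    p <- sample(nchar(read), 1L)
    op <- sample(c("sub", "ins", "del"), 1L)
    if (op == "sub") {
      ref <- substr(read, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      substr(read, p, p) <- alt
    } else if (op == "ins") {
      read <- paste0(substr(read, 1L, p), sample(c("A", "C", "G", "T"), 1L),
                     substr(read, p + 1L, nchar(read)))
    } else if (nchar(read) > 1L) {
      read <- paste0(substr(read, 1L, p - 1L),
                     substr(read, p + 1L, nchar(read)))
    }
  }
  read
}

#' Sample reads with planted errors from a synthetic pan-genome
#'
#' Each read is an exact substring of a uniformly chosen strain, then
#' receives 0..`planted_errors` planted edits (substitutions and indels).
#' The true locus and number of planted edits are recorded.
#'
#' @param text A [pan_genome_text].
#' @param cfg A [synth_config] (supplies `read_length`, `n_reads`,
#'   `planted_errors` and the seed; the read seed is offset so reads differ
#'   from the genome stream).
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `strain`, `pos` — 0-based within the strain —
#'   `planted_ed`).
#' @export
sample_reads <- function(text, cfg) {
  stopifnot(inherits(text, "pan_genome_text"), inherits(cfg, "synth_config"))
  if (cfg$read_length > min(text$seq_lens))
    stop("read_length exceeds the shortest sequence")
  with_seed(cfg$seed + 104729L, {
    reads <- character(cfg$n_reads)
    strain <- integer(cfg$n_reads)
    pos <- integer(cfg$n_reads)
    ped <- integer(cfg$n_reads)
    bodies <- strsplit(text$T, "[%$]")[[1L]]
    for (i in seq_len(cfg$n_reads)) {
      s <- sample(text$S, 1L) - 1L
      p <- sample(text$seq_lens[s + 1L] - cfg$read_length + 1L, 1L) - 1L
      rd <- substr(bodies[s + 1L], p + 1L, p + cfg$read_length)
      e <- sample(0:cfg$planted_errors, 1L)
      reads[i] <- plant_edits(rd, e)
      strain[i] <- s; pos[i] <- p; ped[i] <- e
    }
    names(reads) <- sprintf("read_%04d", seq_len(cfg$n_reads) - 1L)
    list(reads = reads,
         truth = data.frame(read_id = names(reads), strain = strain,
                            pos = pos, planted_ed = ped))
  })
}
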