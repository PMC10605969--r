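# Worked-example fixture: T = "CTATGTC%ATATGTTGGTC$" (two strains), k = 3.
# The frozen vectors below are the reference tables for this text:
# suffix arrays, BWTs and LF mappings of both directions, the marker bit
# vectors, the node attribute table and both rank-to-identifier maps
# (including the checkpoint-extended map for s_cp = 2).

example_text <- function() pan_genome_text(c("CTATGTC", "ATATGTTGGTC"))

example_index <- function(s_SA = 1L) build_index(example_text(), s_SA = s_SA)

EX_T <- "CTATGTC%ATATGTTGGTC$"
EX_TR <- "$CTGGTTGTATA%CTGTATC"

EX_SA  <- c(19L, 7L, 8L, 2L, 10L, 18L, 6L, 0L, 15L, 16L, 4L, 12L, 1L, 9L,
            17L, 5L, 14L, 3L, 11L, 13L)
EX_BWT <- "CC%TTTT$TGTTCAGGTAAG"
EX_LF  <- c(5L, 6L, 1L, 12L, 13L, 14L, 15L, 0L, 16L, 8L, 17L, 18L, 7L, 2L,
            9L, 10L, 19L, 3L, 4L, 11L)
EX_B_BASE <- c(0L, 1L, 2L, 7L, 8L, 10L, 18L)       # rightmost-k-mer bits
EX_B_CP2  <- sort(c(EX_B_BASE, 13L, 11L, 16L))     # + checkpoints, s_cp = 2

EX_SAR  <- c(0L, 12L, 11L, 9L, 17L, 19L, 1L, 13L, 3L, 7L, 15L, 4L, 10L, 8L,
             16L, 18L, 2L, 6L, 14L, 5L)
EX_BWTR <- "CATTTT$%TTTGAGGACTCG"
EX_LFR  <- c(5L, 2L, 12L, 13L, 14L, 15L, 0L, 1L, 16L, 17L, 18L, 8L, 3L, 9L,
             10L, 4L, 6L, 19L, 7L, 11L)
EX_BR   <- c(0L, 1L, 3L, 4L, 7L, 14L, 19L)

# node attribute table (canonical ids 0..6)
EX_NODES <- data.frame(
  id = 0:6,
  len = c(3L, 5L, 3L, 3L, 6L, 3L, 3L),
  mult = c(2L, 2L, 1L, 1L, 1L, 1L, 1L),
  left_kmer = c(9L, 12L, 2L, 7L, 11L, 14L, 15L),
  right_kmer_r = c(6L, 17L, 3L, 4L, 16L, 15L, 12L),
  omega = c("GTC", "TATGT", "ATA", "CTA", "GTTGGT", "TC$", "TC%"))

EX_IDMAP <- c(5L, 6L, 2L, 3L, 4L, 0L, 1L)           # baseline (no checkpoints)
EX_IDMAP_R <- c(5L, 6L, 2L, 3L, 0L, 1L, 4L)
EX_IDMAP_CP2 <- c(5L, 6L, 2L, 3L, 4L, 0L, 4L, 1L, 4L, 1L)
EX_OFFSET_CP2 <- c(2L, 2L, 0L, 0L, 3L, 0L, 0L, 0L, 2L, 2L)
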