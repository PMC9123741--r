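#' @name synthetic
#' @title Synthetic labelled sequence sets with an implanted domain motif
#'
#' @description
#' A download-free benchmark generator with the statistical structure the
#' pipeline assumes: negatives are i.i.d. background sequences; positives
#' carry a conserved motif (with per-site substitutions at `mutation_rate`)
#' at a fixed offset inside a designated "non-cytoplasmic" region, so the
#' positives align over that region without gaps by construction. The
#' generator returns the labelled dataset, the positives' alignment and the
#' region annotation on a reference positive — exactly the inputs the
#' feature-extraction and profile code consume.
#'
#' `mutation_rate` is the difficulty dial: at 0 the motif is exact and the
#' profile-HMM score alone separates the classes; separability degrades
#' monotonically as the rate approaches 0.5.
NULL

#' Synthetic dataset configuration
#'
#' @param n_pos,n_neg class sizes (`n_pos >= 2`).
#' @param length_range integer range of sequence lengths.
#' @param background named residue frequencies (default uniform over the 20
#'   standard residues; `"robinson"` selects Robinson-Robinson-style
#'   frequencies).
#' @param motif residue string implanted in positives.
#' @param motif_region `(start, end)` interval (1-based inclusive) acting as
#'   the non-cytoplasmic domain; must contain the motif and fit within the
#'   minimum sequence length.
#' @param mutation_rate per-site substitution probability on the implanted
#'   motif, in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return list of class `xt_synth_config`.
#' @export
synth_config <- function(n_pos = 25L, n_neg = 371L,
                         length_range = c(400L, 600L),
                         background = "uniform",
                         motif = "WYHKRNDEQWFHCMP",
                         motif_region = c(41L, 90L),
                         mutation_rate = 0.1, seed = 1L) {
  stopifnot(n_pos >= 2L, n_neg >= 1L, length(length_range) == 2L,
            length_range[[1L]] <= length_range[[2L]],
            mutation_rate >= 0, mutation_rate < 0.5)
  if (identical(background, "uniform")) {
    background <- setNames(rep(1 / 20, 20L), AA20)
  } else if (identical(background, "robinson")) {
    background <- robinson_frequencies()
  }
  background <- background[AA20] / sum(background[AA20])
  region_len <- motif_region[[2L]] - motif_region[[1L]] + 1L
  if (nchar(motif) > region_len) stop("motif does not fit in motif_region")
  if (motif_region[[2L]] > length_range[[1L]]) {
    stop("motif_region exceeds the minimum sequence length")
  }
  if (motif_region[[1L]] < 1L) stop("motif_region must start at >= 1")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 background = background, motif = toupper(motif),
                 motif_region = as.integer(motif_region),
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "xt_synth_config")
}

# Robinson & Robinson style average residue frequencies
robinson_frequencies <- function() {
  f <- c(A = 7.8, C = 1.9, D = 5.4, E = 6.3, F = 3.9, G = 7.4, H = 2.2,
         I = 5.1, K = 5.7, L = 9.0, M = 2.2, N = 4.5, P = 5.2, Q = 4.3,
         R = 5.1, S = 7.1, T = 5.8, V = 6.4, W = 1.4, Y = 3.2)
  f / sum(f)
}

#' Generate a synthetic labelled dataset, positives MSA and annotation
#'
#' @param cfg [synth_config()].
#' @return list of class `xt_synth` with `dataset` (`xt_dataset`), `msa`
#'   (`xt_msa` of the positives, reference = first positive; shorter rows
#'   padded with trailing gaps) and `regions` (`xt_regions` marking the
#'   motif region as `non_cytoplasmic` on the reference).
#' @export
synth_generate <- function(cfg = synth_config()) {
  with_seed(cfg$seed, {
    rand_seq <- function(L) {
      paste0(sample(AA20, L, replace = TRUE, prob = cfg$background),
             collapse = "")
    }
    lens <- sample(seq(cfg$length_range[[1L]], cfg$length_range[[2L]]),
                   cfg$n_pos + cfg$n_neg, replace = TRUE)
    motif_chars <- strsplit(cfg$motif, "")[[1L]]
    mstart <- cfg$motif_region[[1L]] +
      ((cfg$motif_region[[2L]] - cfg$motif_region[[1L]] + 1L -
          length(motif_chars)) %/% 2L)
    seqs <- character(cfg$n_pos + cfg$n_neg)
    for (i in seq_len(cfg$n_pos + cfg$n_neg)) {
      s <- rand_seq(lens[[i]])
      if (i <= cfg$n_pos) {
        m <- motif_chars
        mut <- runif(length(m)) < cfg$mutation_rate
        if (any(mut)) {
          m[mut] <- vapply(m[mut], function(ch)
            sample(setdiff(AA20, ch), 1L), character(1))
        }
        substr(s, mstart, mstart + length(m) - 1L) <- paste0(m, collapse = "")
      }
      seqs[[i]] <- s
    }
    ids <- c(sprintf("pos%03d", seq_len(cfg$n_pos)),
             sprintf("neg%03d", seq_len(cfg$n_neg)))
    records <- xt_sequences(ids, seqs)
    labels <- setNames(c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg)), ids)
    dataset <- xt_dataset(records, labels)

    pos_seqs <- seqs[seq_len(cfg$n_pos)]
    w <- max(nchar(pos_seqs))
    aligned <- vapply(pos_seqs, function(s)
      paste0(s, strrep("-", w - nchar(s))), character(1))
    msa <- xt_msa(ids[seq_len(cfg$n_pos)], unname(aligned),
                  reference_id = ids[[1L]])
    regions <- xt_regions(ids[[1L]],
                          data.frame(start = cfg$motif_region[[1L]],
                                     end = cfg$motif_region[[2L]],
                                     kind = "non_cytoplasmic"),
                          reference_length = nchar(pos_seqs[[1L]]))
    structure(list(dataset = dataset, msa = msa, regions = regions,
                   config = cfg),
              class = "xt_synth")
  })
}

#' The standard benchmark fixture
#'
#' One call yields the canonical class-imbalance shape: 25 positives / 371
#' negatives (396 sequences in total), lengths 400-600, a 15-residue motif
#' with per-site mutation rate 0.1.
#'
#' @param seed RNG seed.
#' @return [synth_generate()] output.
#' @export
default_paper_shape <- function(seed = 1L) {
  synth_generate(synth_config(n_pos = 25L, n_neg = 371L,
                              length_range = c(400L, 600L),
                              motif = "WYHKRNDEQWFHCMP",
                              motif_region = c(41L, 90L),
                              mutation_rate = 0.1, seed = seed))
}

#' Write synthetic fixtures to a directory
#' @param synth `xt_synth`; `dir` output directory.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; writes `sequences.fa`, `labels.tsv`,
#'   `positives.aln.fa`, `regions.json`.
#' @export
write_synth <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(synth$dataset$records, file.path(dir, "sequences.fa"))
  utils::write.table(
    data.frame(id = names(synth$dataset$labels),
               label = as.integer(synth$dataset$labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_fasta(synth$msa, file.path(dir, "positives.aln.fa"))
  write_regions(synth$regions, file.path(dir, "regions.json"))
  invisible(dir)
}
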