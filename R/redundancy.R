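#' @name redundancy
#' @title Greedy identity-based redundancy removal
#'
#' @description
#' A CD-HIT-style greedy clustering at a sequence-identity threshold
#' (default 80%): sequences are visited in order of decreasing length (ties
#' broken by id) and join the first existing representative they match at or
#' above the threshold, otherwise they found a new cluster. Known xylose
#' transporters can be *protected*: any protected sequence removed by
#' clustering is re-added to the output afterwards.
#'
#' Identity is the CD-HIT convention: the number of identical positions in a
#' global alignment (BLOSUM62, gap open 10 / extend 1) divided by the length
#' of the shorter sequence.
NULL

#' Pairwise sequence identity
#' @param a,b residue strings (non-empty).
#' @return fraction in `[0, 1]`; symmetric.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1,
    type = "global")
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

#' Greedy redundancy clustering with protected ids
#'
#' @param data an `xt_dataset` or `xt_sequences`.
#' @param threshold identity threshold in (0, 1); default 0.8.
#' @param protected character vector of ids that must survive (typically the
#'   known xylose transporters).
#' @return list of class `xt_clusters`: `representatives` (ids, in creation
#'   order), `members` (named list: representative -> member ids, each input
#'   id appearing exactly once), `protected`, and `kept` — the ids retained
#'   in the output (representatives plus re-added protected ids).
#' @export
greedy_cluster <- function(data, threshold = 0.8, protected = character(0)) {
  stopifnot(threshold > 0, threshold < 1)
  records <- if (inherits(data, "xt_dataset")) data$records else data
  missing <- setdiff(protected, records$id)
  if (length(missing)) {
    stop("protected id(s) not in dataset: ", paste(missing, collapse = ", "))
  }
  ord <- order(-nchar(records$residues), records$id)
  ids <- records$id[ord]
  seqs <- records$residues[ord]

  reps <- character(0)
  rep_seqs <- character(0)
  members <- list()
  for (i in seq_along(ids)) {
    joined <- FALSE
    if (length(reps)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(rep_seqs), Biostrings::AAString(seqs[[i]]),
        substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1,
        type = "global")
      ident <- Biostrings::nmatch(pa) /
        pmin(nchar(rep_seqs), nchar(seqs[[i]]))
      hit <- which(ident >= threshold)
      if (length(hit)) {
        r <- reps[[hit[[1L]]]]
        members[[r]] <- c(members[[r]], ids[[i]])
        joined <- TRUE
      }
    }
    if (!joined) {
      reps <- c(reps, ids[[i]])
      rep_seqs <- c(rep_seqs, seqs[[i]])
      members[[ids[[i]]]] <- ids[[i]]
    }
  }
  kept <- union(reps, intersect(protected, records$id))
  removed_protected <- setdiff(intersect(protected, records$id), reps)
  if (length(removed_protected)) {
    logmsg("re-added ", length(removed_protected),
           " protected sequence(s) removed by clustering")
  }
  structure(list(representatives = reps, members = members,
                 protected = protected, kept = kept,
                 threshold = threshold),
            class = "xt_clusters")
}

#' @export
print.xt_clusters <- function(x, ...) {
  cat("Greedy clustering at identity >=", x$threshold, ":",
      length(x$representatives), "representatives;",
      length(x$kept), "sequences kept\n")
  invisible(x)
}

#' Apply a clustering result to a dataset
#' @param data `xt_dataset` or `xt_sequences`.
#' @param clusters `xt_clusters` from [greedy_cluster()].
#' @return the input restricted to the kept ids (original record order).
#' @export
cluster_filter <- function(data, clusters) {
  if (inherits(data, "xt_dataset")) {
    keep <- data$records$id %in% clusters$kept
    rec <- data$records[keep, , drop = FALSE]
    class(rec) <- c("xt_sequences", "data.frame")
    xt_dataset(rec, data$labels[keep])
  } else {
    out <- data[data$id %in% clusters$kept, , drop = FALSE]
    class(out) <- c("xt_sequences", "data.frame")
    out
  }
}
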