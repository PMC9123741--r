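#' @name seqio
#' @title Sequence, label and region-annotation input/output
#'
#' @description
#' Readers and writers for the file formats the pipeline consumes: plain and
#' gapped (aligned) FASTA, id/label TSV, JSON or BED region annotations, and
#' the TSV feature matrix. All residue strings are normalised to uppercase;
#' the translation stop `*` is stripped; the ambiguous residues B, Z, U, O are
#' mapped to `X`, which descriptor code later excludes from composition
#' denominators. Region coordinates are 1-based inclusive in the ungapped
#' reference sequence, the convention of Uniprot/InterPro annotations.
NULL

# ---- residue normalisation -------------------------------------------------

normalize_residues <- function(x, gapped = FALSE, id = "?") {
  x <- toupper(x)
  x <- gsub("*", "", x, fixed = TRUE)
  x <- chartr("BZUO", "XXXX", x)
  if (!gapped && grepl("-", x, fixed = TRUE)) {
    stop("sequence '", id,
         "' contains gap characters; use gapped = TRUE for alignments")
  }
  ok <- paste0(AA20, collapse = "")
  pat <- if (gapped) sprintf("[^%sX.-]", ok) else sprintf("[^%sX]", ok)
  bad <- regmatches(x, regexpr(pat, x))
  if (length(bad) && nzchar(bad)) {
    stop("sequence '", id, "' contains illegal character '", bad, "'")
  }
  if (gapped) x <- gsub(".", "-", x, fixed = TRUE)
  x
}

#' Remove gap characters from an aligned sequence
#' @param x character vector of aligned residue strings.
#' @return character vector of ungapped residue strings.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

# ---- FASTA -----------------------------------------------------------------

#' Read protein sequences or a gapped alignment from FASTA
#'
#' @param path FASTA file.
#' @param gapped if `TRUE` the file is a multiple sequence alignment; all rows
#'   must have equal aligned length and an [xt_msa] is returned.
#' @param reference_id optional row id to mark as the alignment reference
#'   (only with `gapped = TRUE`).
#' @return For `gapped = FALSE` a data frame of class `xt_sequences` with
#'   columns `id`, `description`, `residues`; otherwise an `xt_msa`.
#' @export
read_fasta <- function(path, gapped = FALSE, reference_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  res <- as.character(set)
  res <- vapply(seq_along(res), function(i) {
    normalize_residues(res[[i]], gapped = gapped, id = id[[i]])
  }, character(1))
  if (any(!nzchar(degap(res)))) {
    stop("empty sequence for id(s): ",
         paste(id[!nzchar(degap(res))], collapse = ", "))
  }
  if (gapped) {
    if (length(unique(nchar(res))) != 1L) {
      stop("ragged alignment: aligned lengths differ")
    }
    return(xt_msa(id, res, reference_id = reference_id))
  }
  if (any(grepl("-", res, fixed = TRUE))) {
    stop("gap characters present; use gapped = TRUE for alignments")
  }
  xt_sequences(id, res, desc)
}

#' Construct a sequence table
#' @param id,residues,description character vectors of equal length.
#' @return data frame of class `xt_sequences`.
#' @export
xt_sequences <- function(id, residues, description = "") {
  stopifnot(length(id) == length(residues))
  if (anyDuplicated(id)) stop("duplicate sequence ids")
  if (any(!nzchar(id))) stop("empty sequence id")
  if (any(!nzchar(residues))) stop("empty residue string")
  out <- data.frame(id = as.character(id),
                    description = rep_len(as.character(description), length(id)),
                    residues = as.character(residues),
                    stringsAsFactors = FALSE)
  class(out) <- c("xt_sequences", "data.frame")
  out
}

#' Write sequences to FASTA
#' @param x an `xt_sequences` data frame or an `xt_msa`.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "xt_msa")) {
    ids <- x$ids; seqs <- x$aligned; desc <- rep("", length(ids))
  } else {
    ids <- x$id; seqs <- x$residues; desc <- x$description
  }
  hdr <- ifelse(nzchar(desc), paste(ids, desc), ids)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", hdr[[i]]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- MSA -------------------------------------------------------------------

#' Multiple sequence alignment container
#' @param ids row ids; `aligned` equal-length residue strings with `-` gaps.
#' @param aligned character vector of aligned rows.
#' @param reference_id optional id of the coordinate reference row.
#' @return list of class `xt_msa` with elements `ids`, `aligned` (named),
#'   `reference_id`, `width`.
#' @export
xt_msa <- function(ids, aligned, reference_id = NULL) {
  stopifnot(length(ids) == length(aligned))
  if (anyDuplicated(ids)) stop("duplicate alignment row ids")
  w <- unique(nchar(aligned))
  if (length(w) != 1L) stop("ragged alignment: aligned lengths differ")
  if (!is.null(reference_id) && !reference_id %in% ids) {
    stop("reference_id '", reference_id, "' not among alignment rows")
  }
  structure(list(ids = as.character(ids),
                 aligned = setNames(as.character(aligned), ids),
                 reference_id = reference_id,
                 width = w),
            class = "xt_msa")
}

#' @export
print.xt_msa <- function(x, ...) {
  cat("Multiple sequence alignment:", length(x$ids), "rows x", x$width,
      "columns\n")
  if (!is.null(x$reference_id)) cat("reference row:", x$reference_id, "\n")
  invisible(x)
}

# ---- labels ----------------------------------------------------------------

#' Attach binary xylose-transport labels to sequences
#'
#' Reads a two-column TSV (`id`, `label` with label in \{0, 1\}; 1 marks a
#' xylose transporter) and pairs it with a sequence table, reporting class
#' counts.
#'
#' @param path TSV file with header columns `id` and `label`.
#' @param records an `xt_sequences` data frame.
#' @return list of class `xt_dataset` with elements `records` and `labels`
#'   (named integer vector over record ids).
#' @export
load_labels <- function(path, records) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  if (!all(c("id", "label") %in% names(tab))) {
    stop("label TSV must have columns 'id' and 'label'")
  }
  if (anyDuplicated(tab$id)) stop("duplicate ids in label file")
  lab <- suppressWarnings(as.integer(tab$label))
  if (any(is.na(lab)) || !all(lab %in% c(0L, 1L))) {
    bad <- tab$id[is.na(lab) | !lab %in% c(0L, 1L)]
    stop("label outside {0,1} for id(s): ", paste(bad, collapse = ", "))
  }
  miss <- setdiff(records$id, tab$id)
  if (length(miss)) stop("missing label for id(s): ", paste(miss, collapse = ", "))
  labels <- setNames(lab[match(records$id, tab$id)], records$id)
  xt_dataset(records, labels)
}

#' Labelled sequence dataset
#' @param records `xt_sequences`; `labels` named 0/1 integer vector over ids.
#' @param labels named integer vector.
#' @return list of class `xt_dataset`.
#' @export
xt_dataset <- function(records, labels) {
  stopifnot(inherits(records, "xt_sequences"))
  labels <- labels[records$id]
  if (any(is.na(labels))) stop("missing label for some record ids")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  labels <- setNames(as.integer(labels), records$id)
  out <- structure(list(records = records, labels = labels),
                   class = "xt_dataset")
  logmsg("dataset: ", sum(labels == 1L), " positive / ",
         sum(labels == 0L), " negative sequences")
  out
}

#' @export
print.xt_dataset <- function(x, ...) {
  cat("Labelled dataset:", nrow(x$records), "sequences (",
      sum(x$labels == 1L), "positive /", sum(x$labels == 0L), "negative )\n")
  invisible(x)
}

# ---- region annotations ----------------------------------------------------

REGION_KINDS <- c("non_cytoplasmic", "binding_site")

#' Region annotation container
#'
#' Regions are intervals of the *ungapped* reference sequence, 1-based and
#' inclusive at both ends, each tagged `non_cytoplasmic` or `binding_site`.
#'
#' @param reference_id id of the reference sequence/alignment row.
#' @param regions data frame with columns `start`, `end`, `kind`.
#' @param reference_length optional known ungapped reference length used to
#'   validate interval bounds.
#' @return list of class `xt_regions`.
#' @export
xt_regions <- function(reference_id, regions, reference_length = NULL) {
  stopifnot(is.character(reference_id), length(reference_id) == 1L)
  regions <- as.data.frame(regions)[, c("start", "end", "kind")]
  if (nrow(regions) == 0L) stop("at least one region is required")
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  regions$kind <- as.character(regions$kind)
  if (!all(regions$kind %in% REGION_KINDS)) {
    stop("region kind must be one of: ", paste(REGION_KINDS, collapse = ", "))
  }
  if (any(regions$start < 1L) || any(regions$end < regions$start)) {
    stop("regions must satisfy 1 <= start <= end")
  }
  if (!is.null(reference_length) && any(regions$end > reference_length)) {
    stop("region end exceeds ungapped reference length (", reference_length, ")")
  }
  o <- order(regions$start, regions$end)
  regions <- regions[o, , drop = FALSE]
  if (nrow(regions) > 1L &&
      any(regions$start[-1L] <= regions$end[-nrow(regions)])) {
    stop("regions overlap after sorting")
  }
  rownames(regions) <- NULL
  structure(list(reference_id = reference_id, regions = regions),
            class = "xt_regions")
}

#' Read a JSON region-annotation file
#'
#' Expected shape: `{"reference_id": "...", "regions": [{"start": 1,
#' "end": 30, "kind": "non_cytoplasmic"}, ...]}` with 1-based inclusive
#' coordinates.
#'
#' @param path JSON file.
#' @param reference_length optional ungapped reference length for validation.
#' @return `xt_regions`.
#' @export
read_regions <- function(path, reference_length = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$reference_id) || is.null(obj$regions)) {
    stop("region JSON needs 'reference_id' and 'regions'")
  }
  xt_regions(obj$reference_id, obj$regions, reference_length)
}

#' Write regions to JSON
#' @param regions `xt_regions`; `path` output file.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  jsonlite::write_json(list(reference_id = regions$reference_id,
                            regions = regions$regions),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read regions from a BED-dialect file
#'
#' Columns: reference id, start, end, kind. BED uses 0-based half-open
#' intervals; they are converted to the package's 1-based inclusive
#' convention on load (`start + 1`, `end` unchanged).
#'
#' @param path BED file (tab separated, no header).
#' @param reference_length optional ungapped reference length for validation.
#' @return `xt_regions`.
#' @export
read_regions_bed <- function(path, reference_length = NULL) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = c("character", "integer", "integer",
                                   "character"))
  names(tab) <- c("reference_id", "start", "end", "kind")
  ref <- unique(tab$reference_id)
  if (length(ref) != 1L) stop("BED region file must use a single reference id")
  xt_regions(ref, data.frame(start = tab$start + 1L, end = tab$end,
                             kind = tab$kind), reference_length)
}

# ---- feature matrix I/O ----------------------------------------------------

#' Write a feature matrix to TSV
#'
#' @param matrix numeric matrix with row names (sequence ids) and unique
#'   column names (features). Values must be finite.
#' @param path output TSV file; first column `id`, then one column per
#'   feature, full double precision (round-trips via [read_features()]).
#' @return `path`, invisibly.
#' @export
write_features <- function(matrix, path) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (any(!is.finite(matrix))) stop("feature matrix contains NaN/Inf/NA values")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("feature matrix needs row and column names")
  }
  df <- data.frame(id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path TSV file.
#' @return numeric matrix with ids as row names.
#' @export
read_features <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}
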