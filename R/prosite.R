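#' @name prosite
#' @title PROSITE signature pattern matching
#'
#' @description
#' A local matcher for the PROSITE pattern language used by sugar-transport
#' signatures: elements separated by `-`, residue sets `[..]`, excluded sets
#' `{..}`, the wildcard `x`, repetitions `(n)` / `(n,m)`, the anchors `<`
#' (N-terminus) and `>` (C-terminus), and an optional trailing period.
#' Scans are overlapping: the match count is the number of start positions
#' at which the pattern matches.
NULL

#' Compile a PROSITE-syntax pattern
#'
#' @param raw pattern string, e.g. `"G-[LIVM]-x(2)-C"`.
#' @return list of class `xt_prosite` with fields `raw` and `regex`.
#' @export
compile_prosite <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  pat <- sub("\\.$", "", trimws(raw))
  anchor_start <- startsWith(pat, "<")
  if (anchor_start) pat <- substring(pat, 2L)
  anchor_end <- endsWith(pat, ">")
  if (anchor_end) pat <- substring(pat, 1L, nchar(pat) - 1L)
  if (!nzchar(pat)) stop("malformed PROSITE pattern: ", raw)
  elements <- strsplit(pat, "-", fixed = TRUE)[[1L]]
  el_rx <- "^([A-Zx]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$"
  parts <- vapply(elements, function(el) {
    m <- regmatches(el, regexec(el_rx, el))[[1L]]
    if (length(m) == 0L) stop("malformed PROSITE element '", el, "' in: ", raw)
    core <- m[[2L]]
    rx <- if (core == "x") {
      "."
    } else if (startsWith(core, "[")) {
      core
    } else if (startsWith(core, "{")) {
      paste0("[^", substring(core, 2L, nchar(core) - 1L), "]")
    } else {
      core
    }
    if (nzchar(m[[3L]])) {
      lo <- m[[4L]]
      hi <- m[[6L]]
      rx <- if (nzchar(hi)) sprintf("%s{%s,%s}", rx, lo, hi)
            else sprintf("%s{%s}", rx, lo)
    }
    rx
  }, character(1))
  regex <- paste0(parts, collapse = "")
  if (anchor_start) regex <- paste0("^", regex)
  if (anchor_end) regex <- paste0(regex, "$")
  structure(list(raw = raw, regex = regex), class = "xt_prosite")
}

#' Start positions of overlapping pattern matches
#' @param pattern an [compile_prosite()] object (or raw pattern string).
#' @param seq residue string.
#' @return integer vector of 1-based match start positions.
#' @export
prosite_match_positions <- function(pattern, seq) {
  if (!inherits(pattern, "xt_prosite")) pattern <- compile_prosite(pattern)
  hits <- gregexpr(paste0("(?=", pattern$regex, ")"), seq, perl = TRUE)[[1L]]
  if (hits[[1L]] == -1L) integer(0) else as.integer(hits)
}

#' Per-pattern match count and presence features
#' @param seq residue string.
#' @param patterns named list of compiled patterns (or raw strings).
#' @return named numeric vector: `prosite.<name>.count` and
#'   `prosite.<name>.present` per pattern.
#' @export
prosite_features <- function(seq, patterns) {
  if (is.null(names(patterns)) || any(!nzchar(names(patterns)))) {
    stop("patterns must be a named list")
  }
  out <- numeric(0)
  for (nm in names(patterns)) {
    n <- length(prosite_match_positions(patterns[[nm]], seq))
    out <- c(out, setNames(c(n, as.numeric(n > 0)),
                           paste0("prosite.", nm, c(".count", ".present"))))
  }
  out
}
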