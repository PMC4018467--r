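# Imperfect microsatellite detection.
#
# A valid repeat run is a maximal perfect tandem tract, possibly merged
# with subsequent tracts of the same canonical motif across interruptions
# of at most max_gap nt. Validity thresholds follow the descriptor rules
# used for the published scan: >= 12 copies for mononucleotide motifs and
# >= 4 copies for di- to hexanucleotide motifs (applied to the floor of
# the real-valued copy number).

# lexicographically smallest rotation of a motif
canonical_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(motif)
  rots <- vapply(seq_len(u), function(k) {
    paste0(substr(motif, k, u), substr(motif, 1, k - 1L))
  }, character(1))
  min(rots)
}

# TRUE if the motif is itself a tandem repeat of a shorter unit
is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        motif == strrep(substr(motif, 1, d), u / d)) {
      return(FALSE)
    }
  }
  TRUE
}

# all maximal perfect tandem tracts with unit length u (>= 2 full units'
# worth of sites, N never matches); returns start/end (1-based inclusive)
perfect_runs <- function(chars, u) {
  n <- length(chars)
  if (n < 2L * u) return(NULL)
  m <- chars[seq_len(n - u)] == chars[(u + 1L):n] &
    chars[seq_len(n - u)] != "N"
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= u
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep], end = ends[keep] + u)
}

#' Detect imperfect microsatellite runs
#'
#' Scans a nucleotide sequence for tandem repeats of unit length 1-6.
#' Perfect tracts of the same canonical motif separated by interruptions
#' of at most `max_gap` nt are merged into one imperfect run. A run is
#' reported when its (floored) copy number reaches the motif-class
#' threshold and its purity (fraction of the spanned bases belonging to
#' perfect tracts) reaches `min_purity`. Overlapping candidates are
#' resolved deterministically: the longer run wins; ties go to the smaller
#' start, then the lexicographically smaller motif.
#'
#' @param sequence Single nucleotide string over `A`,`C`,`G`,`T`,`N`
#'   (`N` breaks runs).
#' @param min_mono Minimum copies for mononucleotide motifs (default 12).
#' @param min_multi Minimum copies for di- to hexanucleotide motifs
#'   (default 4).
#' @param max_gap Maximum interruption length in nt merged across
#'   (default 4, i.e. two dinucleotide units).
#' @param min_purity Minimum run purity in (0, 1] (default 0.85).
#' @return Data frame sorted by start: `motif` (canonical rotation),
#'   `unit_len`, `start`, `end`, `copies` (real-valued, matched length /
#'   unit length), `purity`, `interruptions`.
#' @export
find_repeats <- function(sequence, min_mono = 12L, min_multi = 4L,
                         max_gap = 4L, min_purity = 0.85) {
  stopifnot(length(sequence) == 1L, min_mono >= 1L, min_multi >= 1L,
            max_gap >= 0L, min_purity > 0, min_purity <= 1)
  sequence <- toupper(sequence)
  empty <- data.frame(motif = character(0), unit_len = integer(0),
                      start = integer(0), end = integer(0),
                      copies = numeric(0), purity = numeric(0),
                      interruptions = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c(DNA_BASES, "N"))) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }

  cand <- list()
  for (u in 1:6) {
    pr <- perfect_runs(chars, u)
    if (is.null(pr)) next
    for (k in seq_len(nrow(pr))) {
      motif <- paste(chars[pr$start[k]:(pr$start[k] + u - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        motif = canonical_motif(motif), unit_len = u,
        start = pr$start[k], end = pr$end[k],
        matched = pr$end[k] - pr$start[k] + 1L,
        segments = 1L, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)

  # merge same-motif tracts across interruptions of <= max_gap nt
  merged <- list()
  for (key in unique(paste(cand$motif, cand$unit_len))) {
    g <- cand[paste(cand$motif, cand$unit_len) == key, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    cur <- g[1, ]
    if (nrow(g) > 1L) for (k in 2:nrow(g)) {
      gap <- g$start[k] - cur$end - 1L
      gap_has_n <- gap > 0L &&
        any(chars[(cur$end + 1L):(g$start[k] - 1L)] == "N")
      if (gap >= 0L && gap <= max_gap && !gap_has_n) {
        cur$end <- g$end[k]
        cur$matched <- cur$matched + g$matched[k]
        cur$segments <- cur$segments + 1L
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- g[k, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  runs <- do.call(rbind, merged)

  runs$copies <- runs$matched / runs$unit_len
  runs$purity <- runs$matched / (runs$end - runs$start + 1L)
  runs$interruptions <- runs$segments - 1L
  thr <- ifelse(runs$unit_len == 1L, min_mono, min_multi)
  runs <- runs[floor(runs$copies) >= thr & runs$purity >= min_purity, ,
               drop = FALSE]
  if (!nrow(runs)) return(empty)

  # overlap resolution: longer run wins; ties by start, then motif
  len <- runs$end - runs$start + 1L
  runs <- runs[order(-len, runs$start, runs$motif), , drop = FALSE]
  taken <- rep(FALSE, length(chars))
  keep <- logical(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    span <- runs$start[k]:runs$end[k]
    if (!any(taken[span])) {
      keep[k] <- TRUE
      taken[span] <- TRUE
    }
  }
  runs <- runs[keep, , drop = FALSE]
  runs <- runs[order(runs$start), , drop = FALSE]
  rownames(runs) <- NULL
  runs[, c("motif", "unit_len", "start", "end", "copies", "purity",
           "interruptions")]
}

#' Decompose an STR sector into initial, central and final sectors
#'
#' The central sector is the longest detected run of the (GA) dinucleotide
#' family (canonical motif `AG`), already merged across CT-type
#' interruptions by [find_repeats()]; the initial and final sectors are
#' the remaining 5' and 3' sub-sequences. When no valid GA-family run
#' exists the central sector is empty and `degenerate` is set.
#'
#' @param sequence The STR sector sequence.
#' @param id Optional sequence identifier carried into the annotation.
#' @param runs Optional precomputed [find_repeats()] table for `sequence`.
#' @param family Central repeat family motif (default `"GA"`).
#' @param ... Passed to [find_repeats()] when `runs` is not supplied.
#' @return An object of class `str_annotation`: list with `id`, the three
#'   sector ranges and strings, `central_motif`, `copies`,
#'   `interruptions`, `total_length` and `degenerate`.
#' @export
decompose_str <- function(sequence, id = NA_character_, runs = NULL,
                          family = "GA", ...) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (is.null(runs)) runs <- find_repeats(sequence, ...)
  fam <- canonical_motif(family)
  hit <- runs[runs$motif == fam & runs$unit_len == nchar(fam), , drop = FALSE]
  if (!nrow(hit)) {
    ann <- list(id = id, initial = list(start = 1L, end = n,
                                        sequence = sequence),
                central = list(start = NA_integer_, end = NA_integer_,
                               sequence = ""),
                final = list(start = NA_integer_, end = NA_integer_,
                             sequence = ""),
                central_motif = family, copies = 0, interruptions = 0L,
                total_length = n, degenerate = TRUE)
    return(structure(ann, class = "str_annotation"))
  }
  best <- hit[which.max(hit$end - hit$start), ]
  s <- best$start
  e <- best$end
  ann <- list(
    id = id,
    initial = list(start = 1L, end = s - 1L,
                   sequence = substr(sequence, 1L, s - 1L)),
    central = list(start = s, end = e,
                   sequence = substr(sequence, s, e)),
    final = list(start = e + 1L, end = n,
                 sequence = substr(sequence, e + 1L, n)),
    central_motif = family, copies = best$copies,
    interruptions = best$interruptions, total_length = n,
    degenerate = FALSE
  )
  structure(ann, class = "str_annotation")
}

#' @export
print.str_annotation <- function(x, ...) {
  cat(sprintf(
    "STR annotation%s: %d nt = initial %d + central %d (%s, %.1f copies, %d interruptions) + final %d\n",
    if (is.na(x$id)) "" else paste0(" [", x$id, "]"),
    x$total_length, nchar(x$initial$sequence), nchar(x$central$sequence),
    x$central_motif, x$copies, x$interruptions, nchar(x$final$sequence)))
  invisible(x)
}

#' Tabulate STR annotations
#'
#' @param annotations List of [decompose_str()] results.
#' @return Data frame: one row per sequence with id, total length, the
#'   three sector lengths, central motif, copies and interruptions.
#' @export
str_report <- function(annotations) {
  if (inherits(annotations, "str_annotation")) {
    annotations <- list(annotations)
  }
  stopifnot(length(annotations) >= 1L)
  do.call(rbind, lapply(annotations, function(a) {
    data.frame(
      id = a$id, total_length = a$total_length,
      initial_length = nchar(a$initial$sequence),
      central_length = nchar(a$central$sequence),
      final_length = nchar(a$final$sequence),
      central_motif = a$central_motif, copies = a$copies,
      interruptions = a$interruptions, degenerate = a$degenerate,
      stringsAsFactors = FALSE
    )
  }))
}

#' Annotate every STR sector of a panel
#'
#' @param panel A `drb_panel` (or named character vector of STR
#'   sequences).
#' @param ... Passed to [find_repeats()].
#' @return Data frame as [str_report()].
#' @export
scan_panel <- function(panel, ...) {
  strs <- if (inherits(panel, "drb_panel")) panel$str else panel
  str_report(lapply(names(strs), function(id) {
    decompose_str(strs[[id]], id = id, ...)
  }))
}
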