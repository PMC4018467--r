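#' Sector scheme: named column ranges over an amplicon alignment
#'
#' Coordinates are 1-based and inclusive at the interface (the convention
#' used when citing alignment positions such as "exon 2, positions
#' 16-285"); ranges must be contiguous, non-overlapping and strictly
#' increasing.
#'
#' @param names Character vector of sector names.
#' @param starts,ends Integer vectors of 1-based inclusive column ranges.
#' @return An object of class `sector_scheme`.
#' @export
sector_scheme <- function(names, starts, ends) {
  stopifnot(length(names) == length(starts), length(starts) == length(ends))
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  if (any(ends < starts)) stop("sector end before start", call. = FALSE)
  if (anyDuplicated(names)) stop("duplicate sector names", call. = FALSE)
  if (length(starts) > 1L) {
    if (starts[1] != 1L || any(starts[-1L] != head(ends, -1L) + 1L)) {
      stop("sector ranges must be contiguous from column 1", call. = FALSE)
    }
  } else if (starts[1] != 1L) {
    stop("sector ranges must start at column 1", call. = FALSE)
  }
  structure(
    data.frame(sector = as.character(names), start = starts, end = ends,
               stringsAsFactors = FALSE),
    class = c("sector_scheme", "data.frame")
  )
}

#' The five-sector amplicon scheme
#'
#' The published partition of the 1,378-column exon 2 + partial intron 2
#' amplicon alignment: intron 1 (1-15), exon 2 (16-285), alignable intron
#' sector 2A (286-325), the STR sector 2R (326-1110), and alignable intron
#' sector 2B (1111-1378).
#'
#' @return A [sector_scheme()].
#' @export
default_sector_scheme <- function() {
  sector_scheme(
    names = c("intron1", "exon2", "intron2A", "intron2R", "intron2B"),
    starts = c(1L, 16L, 286L, 326L, 1111L),
    ends = c(15L, 285L, 325L, 1110L, 1378L)
  )
}

#' Sector widths implied by a scheme
#' @param scheme A [sector_scheme()].
#' @return Named integer vector of site counts (end - start + 1).
#' @export
sector_widths <- function(scheme) {
  stopifnot(inherits(scheme, "sector_scheme"))
  setNames(scheme$end - scheme$start + 1L, scheme$sector)
}

# normalise an alignment argument to a character matrix of single columns
as_alignment_matrix <- function(alignment) {
  if (inherits(alignment, "DNAbin")) {
    alignment <- toupper(as.character(alignment))
  }
  if (is.character(alignment) && is.null(dim(alignment))) {
    n <- unique(nchar(alignment))
    if (length(n) != 1L) {
      stop("alignment rows must all have equal length", call. = FALSE)
    }
    m <- t(vapply(strsplit(toupper(alignment), "", fixed = TRUE),
                  identity, character(n)))
    rownames(m) <- names(alignment)
    alignment <- m
  }
  if (!is.matrix(alignment) || !is.character(alignment)) {
    stop("alignment must be a character matrix, character vector or DNAbin",
         call. = FALSE)
  }
  alignment
}

#' Partition an alignment into named sectors
#'
#' Splits the columns of an aligned amplicon matrix by a [sector_scheme()].
#' The partition is lossless: concatenating the sectors in scheme order
#' reconstitutes the input alignment exactly.
#'
#' @param alignment Character matrix (rows = sequences), named character
#'   vector of equal-length aligned strings, or an `ape::DNAbin` matrix.
#' @param scheme A [sector_scheme()]; the alignment must have at least as
#'   many columns as the scheme's last coordinate.
#' @return An object of class `sector_partition`: list with `scheme`,
#'   `sectors` (named list of character matrices) and `n_col`.
#' @export
partition_alignment <- function(alignment, scheme = default_sector_scheme()) {
  m <- as_alignment_matrix(alignment)
  last <- max(scheme$end)
  if (ncol(m) < last) {
    bad <- scheme$sector[which(scheme$end > ncol(m))[1]]
    stop(sprintf(
      "alignment has %d columns but sector '%s' extends to column %d",
      ncol(m), bad, scheme$end[scheme$sector == bad]), call. = FALSE)
  }
  sectors <- lapply(seq_len(nrow(scheme)), function(i) {
    m[, scheme$start[i]:scheme$end[i], drop = FALSE]
  })
  names(sectors) <- scheme$sector
  structure(list(scheme = scheme, sectors = sectors, n_col = ncol(m)),
            class = "sector_partition")
}

#' @export
print.sector_partition <- function(x, ...) {
  w <- vapply(x$sectors, ncol, integer(1))
  cat("sector_partition:",
      paste(sprintf("%s[%d]", names(w), w), collapse = " + "), "\n")
  invisible(x)
}

#' Concatenate sectors of a partition
#'
#' @param partition A [partition_alignment()] result.
#' @param names Sector names to concatenate, joined in scheme order.
#' @return Character matrix of the selected columns.
#' @export
concat_sectors <- function(partition, names) {
  stopifnot(inherits(partition, "sector_partition"))
  unknown <- setdiff(names, partition$scheme$sector)
  if (length(unknown)) {
    stop("unknown sector name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- partition$scheme$sector[partition$scheme$sector %in% names]
  do.call(cbind, partition$sectors[keep])
}

#' Mean pairwise percent identity of a sub-alignment
#'
#' Identity of a pair is the proportion of matching columns among the
#' comparable columns. Under the default gap policy, columns where either
#' sequence carries a gap (`-`) or an `N` are excluded from both numerator
#' and denominator; a pair with no comparable columns contributes identity
#' 0 with a warning. The mean and its dispersion are taken over all
#' unordered sequence pairs.
#'
#' @param sub_alignment Character matrix (or coercible, see
#'   [partition_alignment()]) with >= 2 rows.
#' @param gap_policy `"pairwise"` (default, exclude gap columns per pair)
#'   or `"all"` (count gap columns as mismatches).
#' @return An object of class `identity_stat`: list with `mean`, `se`,
#'   `sd` (all on the 0-100 percent scale) and `n_pairs`.
#' @export
pairwise_identity <- function(sub_alignment, gap_policy = c("pairwise", "all")) {
  gap_policy <- match.arg(gap_policy)
  m <- as_alignment_matrix(sub_alignment)
  n <- nrow(m)
  if (n < 2L) stop("pairwise_identity needs >= 2 sequences", call. = FALSE)
  comparable <- m != "-" & m != "N"
  ids <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (gap_policy == "pairwise") {
        use <- comparable[i, ] & comparable[j, ]
        if (!any(use)) {
          warning(sprintf("no comparable columns between rows %d and %d", i, j))
          ids <- c(ids, 0)
          next
        }
        ids <- c(ids, mean(m[i, use] == m[j, use]))
      } else {
        ids <- c(ids, mean(m[i, ] == m[j, ]))
      }
    }
  }
  ids <- 100 * ids
  disp <- if (length(ids) > 1L) sd(ids) else 0
  structure(
    list(mean = mean(ids), sd = disp,
         se = disp / sqrt(length(ids)), n_pairs = length(ids)),
    class = "identity_stat"
  )
}

#' @export
print.identity_stat <- function(x, ...) {
  cat(sprintf("mean pairwise identity %.1f%% (se %.2f, sd %.2f, %d pairs)\n",
              x$mean, x$se, x$sd, x$n_pairs))
  invisible(x)
}

#' Per-sector identity report
#'
#' @param partition A [partition_alignment()] result.
#' @param sectors Sector names to report (default: all).
#' @return Data frame: sector, n_pairs, mean, se, sd.
#' @export
identity_report <- function(partition, sectors = partition$scheme$sector) {
  rows <- lapply(sectors, function(s) {
    st <- pairwise_identity(concat_sectors(partition, s))
    data.frame(sector = s, n_pairs = st$n_pairs, mean = st$mean,
               se = st$se, sd = st$sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read or write a sector scheme as YAML
#' @param scheme A [sector_scheme()].
#' @param path File path.
#' @export
write_sector_scheme <- function(scheme, path) {
  yaml::write_yaml(
    list(sector = scheme$sector, start = scheme$start, end = scheme$end),
    path
  )
  invisible(path)
}

#' @rdname write_sector_scheme
#' @export
read_sector_scheme <- function(path) {
  obj <- yaml::read_yaml(path)
  sector_scheme(obj$sector, obj$start, obj$end)
}
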