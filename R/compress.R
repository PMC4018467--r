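# Alignment-free comparison of STR sectors: tandem amplification followed
# by adaptive Lempel-Ziv (Unix compress .Z) coding. Concatenating a
# sequence with itself before compression lets the adaptive dictionary
# saturate on the sequence's own repeat structure, so the compressed size
# resolves both length and internal complexity.

#' Tandem-amplify a sequence
#'
#' Concatenates `n` copies of the sequence with no separator.
#'
#' @param sequence Single character string.
#' @param n Number of tandem copies (>= 1, default 100).
#' @return The amplified string of `n * nchar(sequence)` characters.
#' @export
tandem <- function(sequence, n = 100L) {
  stopifnot(length(sequence) == 1L, nzchar(sequence), n >= 1L)
  strrep(sequence, as.integer(n))
}

#' Compress or decompress bytes in the Unix compress (.Z) format
#'
#' An adaptive Lempel-Ziv (LZW) coder in the dialect of the classic
#' `compress` utility: 2-byte magic `0x1F 0x9D`, flags byte `0x90`
#' (block mode, 16-bit maximum code), code widths growing from 9 to 16
#' bits, and dictionary reset via the CLEAR code when the compression
#' ratio degrades. Streams are interoperable with the reference decoder
#' (`uncompress` / `gzip -d`). Character input is encoded as ASCII bytes.
#'
#' @param x Bytes to compress: a raw vector or a single character string.
#' @return `compress_lzw()`: the `.Z` stream as a raw vector (3 bytes of
#'   header for empty input). `decompress_lzw()`: the decoded raw vector.
#' @export
compress_lzw <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- charToRaw(x)
  }
  stopifnot(is.raw(x))
  .lzw_compress(x)
}

#' @rdname compress_lzw
#' @param z A `.Z` stream as a raw vector.
#' @export
decompress_lzw <- function(z) {
  stopifnot(is.raw(z))
  .lzw_decompress(z)
}

#' Compression profiles of a sequence panel
#'
#' For each sequence: its uncompressed length `L` in nt, and the size `B`
#' in bytes of the `.Z` stream of the sequence repeated `tandem_factor`
#' times. The compressed payloads are retained (as an attribute) for
#' byte-vector distance mode.
#'
#' @param sequences Named character vector of sequences, or a `drb_panel`
#'   (its STR sectors are profiled).
#' @param tandem_factor Tandem amplification factor (default 100).
#' @return Data frame of class `compression_profile`: `id`, `L`,
#'   `tandem_factor`, `B`; attribute `payloads` holds the raw streams.
#' @export
profile_panel <- function(sequences, tandem_factor = 100L) {
  if (inherits(sequences, "drb_panel")) sequences <- sequences$str
  stopifnot(length(sequences) >= 1L)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  payloads <- lapply(sequences, function(s) {
    compress_lzw(tandem(toupper(s), tandem_factor))
  })
  out <- data.frame(
    id = names(sequences),
    L = nchar(sequences),
    tandem_factor = as.integer(tandem_factor),
    B = vapply(payloads, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "payloads") <- payloads
  class(out) <- c("compression_profile", "data.frame")
  out
}

#' Distance matrix over compression profiles
#'
#' In `size` mode the per-sequence representation is the scalar compressed
#' size, so every metric collapses to `|B_i - B_j|` and the Euclidean,
#' maximum and Manhattan matrices coincide exactly. In `byte_vector` mode
#' the compressed payloads, zero-padded after the 3-byte header to the
#' common maximum length, are compared as numeric vectors under the
#' requested metric.
#'
#' @param profiles A [profile_panel()] result.
#' @param metric `"manhattan"` (default, as in the published complete-
#'   linkage tree), `"euclidean"` or `"maximum"`.
#' @param mode `"size"` (default) or `"byte_vector"`.
#' @return A [stats::dist] object with attributes `metric` and `mode`.
#' @export
distance_matrix <- function(profiles,
                            metric = c("manhattan", "euclidean", "maximum"),
                            mode = c("size", "byte_vector")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  stopifnot(inherits(profiles, "compression_profile"), nrow(profiles) >= 2L)
  if (mode == "size") {
    m <- matrix(as.numeric(profiles$B), ncol = 1,
                dimnames = list(profiles$id, NULL))
  } else {
    payloads <- attr(profiles, "payloads")
    width <- max(vapply(payloads, length, integer(1)))
    m <- t(vapply(payloads, function(p) {
      body <- as.integer(p[-(1:3)])
      c(body, rep(0L, (width - 3L) - length(body)))
    }, numeric(width - 3L)))
    rownames(m) <- profiles$id
  }
  d <- dist(m, method = metric)
  attr(d, "metric") <- metric
  attr(d, "mode") <- mode
  d
}

#' Squared correlation of compressed size with sequence length
#'
#' Ordinary least squares of `B` (compressed bytes) on `L` (sequence
#' length in nt); returns the coefficient of determination.
#'
#' @param profiles A [profile_panel()] result (>= 3 rows).
#' @return R-squared in `[0, 1]`.
#' @export
length_correlation <- function(profiles) {
  stopifnot(inherits(profiles, "compression_profile"), nrow(profiles) >= 3L)
  if (length(unique(profiles$L)) < 2L) {
    stop("length_correlation is undefined for constant L", call. = FALSE)
  }
  summary(lm(B ~ L, data = profiles))$r.squared
}

#' Export helpers for profiles and distance matrices
#'
#' `write_profiles_tsv()` writes the id/L/B table; `write_dist_csv()`
#' writes a square labelled CSV; `write_phylip_dist()` writes the square
#' PHYLIP distance format.
#'
#' @param profiles A [profile_panel()] result.
#' @param d A `dist` object.
#' @param path Output path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  write.table(as.data.frame(profiles), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
write_dist_csv <- function(d, path) {
  write.csv(as.matrix(d), path, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
write_phylip_dist <- function(d, path) {
  m <- as.matrix(d)
  lab <- sprintf("%-10s", substr(rownames(m), 1, 10))
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste(lab[i], paste(sprintf("%.6f", m[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
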