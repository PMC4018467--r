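#' Write panel records to FASTA
#'
#' Headers use the lossless dialect `>id|species|lineage`; `|` is reserved
#' and may not occur inside any of the three fields.
#'
#' @param records A `drb_panel`, or a data frame with columns `id`,
#'   `species`, `lineage`, `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "drb_panel")) records <- records$records
  stopifnot(all(c("id", "species", "lineage", "sequence") %in%
                  colnames(records)))
  meta <- c(records$id, records$species, records$lineage)
  if (any(grepl("|", meta, fixed = TRUE))) {
    stop("'|' is reserved in FASTA header fields", call. = FALSE)
  }
  if (nrow(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- paste(records$id, records$species, records$lineage, sep = "|")
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read panel records from FASTA
#'
#' Inverse of [write_fasta()]: headers of the form `id|species|lineage`
#' are split back into the three fields; a bare header populates `id` and
#' leaves `species`/`lineage` as `NA`.
#'
#' @param path FASTA file path.
#' @return Data frame with columns `id`, `species`, `lineage`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) &&
      !startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop(sprintf("malformed FASTA: line %d is not a header", nonempty[1]),
         call. = FALSE)
  }
  if (!length(nonempty)) {
    return(data.frame(id = character(0), species = character(0),
                      lineage = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  x <- Biostrings::readBStringSet(path)
  fields <- strsplit(names(x), "|", fixed = TRUE)
  getf <- function(k) {
    vapply(fields, function(f) if (length(f) >= k) f[[k]] else NA_character_,
           character(1))
  }
  data.frame(id = unname(getf(1)), species = unname(getf(2)),
             lineage = unname(getf(3)),
             sequence = unname(toupper(as.character(x))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an alignment matrix as FASTA
#' @param alignment Character matrix or named character vector of aligned
#'   strings (gaps as `-`).
#' @param path Output file path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  m <- as_alignment_matrix(alignment)
  seqs <- apply(m, 1, paste, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  names(x) <- rownames(m)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
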