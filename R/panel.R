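#' Lineage specification for the synthetic amplicon generator
#'
#' Describes one MHC-DRB allelic lineage of the synthetic panel: how many
#' alleles it contributes, how far its exon-2/intron prototypes diverge
#' within the lineage, and the structure of its intron-2 microsatellite
#' (central dinucleotide motif, mean and spread of the repeat count, and
#' the rate at which interruption motifs are inserted between repeat
#' units).
#'
#' @param name Lineage label (e.g. `"W18"`, `"DRB3*06"`).
#' @param n_alleles Number of alleles drawn from this lineage (>= 1).
#' @param central_copies_mean,central_copies_sd Mean and standard deviation
#'   of the central repeat-unit count. Draws are rounded Gaussians
#'   truncated at 1 (non-positive draws are redrawn).
#' @param exon_sub_rate Per-site substitution probability applied to the
#'   lineage exon-2 prototype for each allele.
#' @param intron_sub_rate Per-site substitution probability for the
#'   alignable intron sectors (A and B) within the lineage.
#' @param central_motif Dinucleotide repeated in the STR central sector.
#' @param interruption_motif Motif inserted between repeat units as an
#'   interruption.
#' @param interruption_rate Expected interruptions per 10 repeat units.
#' @param species Species tag stamped on this lineage's records, or
#'   `"trans"` to alternate between the two panel species (trans-specific
#'   lineage). Decorative: there is no species-level generative difference.
#'
#' @return An object of class `lineage_spec`.
#' @export
lineage_spec <- function(name,
                         n_alleles = 1L,
                         central_copies_mean = 30,
                         central_copies_sd = 2,
                         exon_sub_rate = 0.008,
                         intron_sub_rate = 0.004,
                         central_motif = "GA",
                         interruption_motif = "CT",
                         interruption_rate = 1,
                         species = "trans") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_alleles <- as.integer(n_alleles)
  if (is.na(n_alleles) || n_alleles < 1L) {
    stop("n_alleles must be >= 1", call. = FALSE)
  }
  if (central_copies_mean <= 0) {
    stop("central_copies_mean must be > 0", call. = FALSE)
  }
  stopifnot(nchar(central_motif) == 2L, interruption_rate >= 0,
            central_copies_sd >= 0)
  structure(
    list(name = name, n_alleles = n_alleles,
         central_copies_mean = central_copies_mean,
         central_copies_sd = central_copies_sd,
         exon_sub_rate = exon_sub_rate,
         intron_sub_rate = intron_sub_rate,
         central_motif = toupper(central_motif),
         interruption_motif = toupper(interruption_motif),
         interruption_rate = interruption_rate,
         species = species),
    class = "lineage_spec"
  )
}

#' Default lineage panel emulating the published 34-allele dataset
#'
#' Eleven lineages whose allele counts and STR-sector length ranges follow
#' the values reported for the two *Aotus* species: a 66-nt STR for the
#' W93-like singleton, 144-160 nt for W18-like alleles, 68-156 nt for the
#' short-STR lineage group (W29/W30/W88/W89/W90/W91), around 294-462 nt
#' for DRB3*06- and DRB1*03GA-like lineages, and a long-STR lineage
#' reaching the 761-nt sector extreme. With 20-nt conserved flanks on each
#' side of the central repeat, a sector of length L corresponds to roughly
#' (L - 40 - 2 * interruptions) / 2 central repeat units.
#'
#' @return A list of [lineage_spec()] objects (34 alleles in total).
#' @export
default_lineages <- function() {
  # interruption densities are lineage-idiosyncratic (the central motif
  # structure characterises lineages), varied around 1 per 10 units
  list(
    lineage_spec("W93",     1L, central_copies_mean = 13,  central_copies_sd = 0,
                 interruption_rate = 0, species = "Aovo"),
    lineage_spec("W18",     3L, central_copies_mean = 52,  central_copies_sd = 3,
                 interruption_rate = 1.2),
    lineage_spec("W29",     3L, central_copies_mean = 30,  central_copies_sd = 2,
                 interruption_rate = 0.8),
    lineage_spec("W30",     2L, central_copies_mean = 38,  central_copies_sd = 2,
                 interruption_rate = 1.0),
    lineage_spec("W88",     1L, central_copies_mean = 25,  species = "Aovo",
                 interruption_rate = 1.4),
    lineage_spec("W89",     2L, central_copies_mean = 16,  central_copies_sd = 1,
                 species = "Aona", interruption_rate = 0.6),
    lineage_spec("W90",     1L, central_copies_mean = 44,  species = "Aovo",
                 interruption_rate = 1.0),
    lineage_spec("W91",     2L, central_copies_mean = 48,  central_copies_sd = 2,
                 interruption_rate = 1.2),
    lineage_spec("DRB3*06", 7L, central_copies_mean = 130, central_copies_sd = 8,
                 interruption_rate = 0.8),
    lineage_spec("DRB1*03GA", 9L, central_copies_mean = 165,
                 central_copies_sd = 25, interruption_rate = 1.2),
    lineage_spec("DRB1*03GB", 3L, central_copies_mean = 320,
                 central_copies_sd = 15, species = "Aona",
                 interruption_rate = 1.0)
  )
}

#' Panel configuration for the synthetic generator
#'
#' @param lineages List of [lineage_spec()] objects.
#' @param seed Integer seed; a fixed seed yields a byte-identical panel.
#' @param between_lineage_exon_divergence Per-site substitution probability
#'   applied independently to each lineage's exon-2 prototype, relative to
#'   the shared base prototype.
#' @param between_lineage_intron_divergence Same, for the alignable intron
#'   sectors.
#' @param str_window Length-2 numeric: admissible `[min, max]` window for
#'   the generated STR sector length in nucleotides (flanks + central
#'   repeats + interruptions). Defaults to the observed sector extremes.
#'
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(lineages = default_lineages(),
                         seed = 1L,
                         between_lineage_exon_divergence = 0.045,
                         between_lineage_intron_divergence = 0.022,
                         str_window = c(66, 761)) {
  if (length(lineages) == 0L) {
    stop("panel_config: lineage list must not be empty", call. = FALSE)
  }
  if (!all(vapply(lineages, inherits, logical(1), "lineage_spec"))) {
    stop("panel_config: all lineages must be lineage_spec objects",
         call. = FALSE)
  }
  stopifnot(length(str_window) == 2L, str_window[1] > 0,
            str_window[2] >= str_window[1])
  structure(
    list(lineages = lineages, seed = as.integer(seed),
         between_lineage_exon_divergence = between_lineage_exon_divergence,
         between_lineage_intron_divergence = between_lineage_intron_divergence,
         str_window = as.numeric(str_window)),
    class = "panel_config"
  )
}

# Fixed panel-wide prototypes. Widths follow the published sector scheme:
# intron 1 stub 15 nt, exon 2 270 nt, intron 2A 40 nt, intron 2B 268 nt.
# The STR flanks (20 nt each side) are conserved across every lineage, as
# observed for the initial/final microsatellite sectors.
panel_prototypes <- function() {
  proto <- with_seed(104729L, {
    list(
      intron1 = paste(sample(DNA_BASES, 15, TRUE), collapse = ""),
      exon2   = paste(sample(DNA_BASES, 270, TRUE), collapse = ""),
      intron2A = paste(sample(DNA_BASES, 40, TRUE), collapse = ""),
      intron2B = paste(sample(DNA_BASES, 268, TRUE), collapse = "")
    )
  })
  proto$str_flank5 <- "TCTCACTCTCTGTCACTGCC"
  proto$str_flank3 <- "CCTTGACCCTCACAGGACTC"
  proto
}

# substitute each site independently with probability rate (new base != old)
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

# central sector: copies of the central motif with interruption motifs
# inserted between repeat units; returns sequence and interruption count
draw_central <- function(spec) {
  copies <- 0L
  for (try in 1:100) {
    copies <- round(rnorm(1, spec$central_copies_mean, spec$central_copies_sd))
    if (copies >= 1) break
  }
  if (copies < 1) copies <- 1L
  # count is proportional to the repeat number (interruption density is a
  # lineage property; alleles of a lineage share complexity and differ
  # chiefly in repeat number); positions are random
  n_int <- if (spec$interruption_rate > 0) {
    as.integer(round(copies * spec$interruption_rate / 10))
  } else 0L
  units <- rep(spec$central_motif, copies)
  # interruptions sit between repeat units, isolated: never in the first or
  # last unit pair and never in adjacent slots (each perfect segment keeps
  # >= 2 units, as in the observed (GA)a CT (GA)b structures)
  allowed <- if (copies >= 4L) seq(2L, copies - 2L) else integer(0)
  at <- integer(0)
  while (n_int > 0L && length(allowed) > 0L) {
    pick <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    at <- c(at, pick)
    allowed <- setdiff(allowed, c(pick - 1L, pick, pick + 1L))
    n_int <- n_int - 1L
  }
  n_int <- length(at)
  if (n_int > 0) {
    at <- sort(at)
    out <- character(0)
    prev <- 0L
    for (a in at) {
      out <- c(out, units[(prev + 1L):a], spec$interruption_motif)
      prev <- a
    }
    out <- c(out, units[(prev + 1L):copies])
    units <- out
  }
  list(sequence = paste(units, collapse = ""), copies = copies,
       interruptions = n_int)
}

#' Generate a lineage-structured synthetic amplicon panel
#'
#' Each record is built as: conserved intron-1 stub, a lineage- and
#' allele-mutated exon 2 (270 nt), the alignable intron sector A (40 nt),
#' the STR sector (conserved 5' flank, central repeats with interruptions,
#' conserved 3' flank), and the alignable intron sector B (268 nt). Exon
#' and intron prototypes diverge between lineages at the configured rates;
#' STR structure varies between lineages chiefly through the central
#' repeat count. The generated STR sector length is constrained to the
#' configured window by redrawing (and finally clamping) the repeat count.
#'
#' @param config A [panel_config()].
#' @return An object of class `drb_panel`: a list with `records` (data
#'   frame: id, species, lineage, sequence), `truth` (data frame: id,
#'   species, lineage, str_length), `str` (named character vector of STR
#'   sectors), `alignment` (character matrix, the gap-padded 1,378-column
#'   panel alignment), and `config`.
#' @export
generate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  proto <- panel_prototypes()
  flank_len <- nchar(proto$str_flank5) + nchar(proto$str_flank3)
  scheme <- default_sector_scheme()
  str_width <- sector_widths(scheme)[["intron2R"]]

  with_seed(config$seed, {
    rec <- list()
    for (spec in config$lineages) {
      lin_exon <- mutate_seq(proto$exon2, config$between_lineage_exon_divergence)
      lin_intrA <- mutate_seq(proto$intron2A,
                              config$between_lineage_intron_divergence)
      lin_intrB <- mutate_seq(proto$intron2B,
                              config$between_lineage_intron_divergence)
      for (a in seq_len(spec$n_alleles)) {
        central <- NULL
        for (try in 1:100) {
          cand <- draw_central(spec)
          len <- flank_len + nchar(cand$sequence)
          if (len >= config$str_window[1] && len <= config$str_window[2] &&
              len <= str_width) {
            central <- cand
            break
          }
        }
        if (is.null(central)) {
          # clamp: largest repeat count fitting the window, no interruptions
          copies <- max(1L, floor((min(config$str_window[2], str_width) -
                                     flank_len) / nchar(spec$central_motif)))
          copies <- min(copies, max(1L, round(spec$central_copies_mean)))
          central <- list(
            sequence = paste(rep(spec$central_motif, copies), collapse = ""),
            copies = copies, interruptions = 0L
          )
        }
        species <- if (identical(spec$species, "trans")) {
          if (a %% 2L == 1L) "Aovo" else "Aona"
        } else {
          spec$species
        }
        str_seq <- paste0(proto$str_flank5, central$sequence, proto$str_flank3)
        id <- sprintf("%s-DRB*%s.%02d", species, gsub("[*]", "", spec$name), a)
        rec[[length(rec) + 1L]] <- list(
          id = id, species = species, lineage = spec$name,
          exon2 = mutate_seq(lin_exon, spec$exon_sub_rate),
          intron2A = mutate_seq(lin_intrA, spec$intron_sub_rate),
          intron2B = mutate_seq(lin_intrB, spec$intron_sub_rate),
          str = str_seq
        )
      }
    }

    ids <- vapply(rec, `[[`, character(1), "id")
    seqs <- vapply(rec, function(r) {
      paste0(proto$intron1, r$exon2, r$intron2A, r$str, r$intron2B)
    }, character(1))
    strs <- setNames(vapply(rec, `[[`, character(1), "str"), ids)
    records <- data.frame(
      id = ids,
      species = vapply(rec, `[[`, character(1), "species"),
      lineage = vapply(rec, `[[`, character(1), "lineage"),
      sequence = seqs,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      id = ids, species = records$species, lineage = records$lineage,
      str_length = nchar(strs), stringsAsFactors = FALSE
    )
    aligned <- t(vapply(rec, function(r) {
      padded_str <- paste0(r$str,
                           strrep("-", str_width - nchar(r$str)))
      strsplit(paste0(proto$intron1, r$exon2, r$intron2A, padded_str,
                      r$intron2B), "", fixed = TRUE)[[1]]
    }, character(sum(sector_widths(scheme)))))
    rownames(aligned) <- ids

    structure(
      list(records = records, truth = truth, str = strs,
           alignment = aligned, config = config),
      class = "drb_panel"
    )
  })
}

#' @export
print.drb_panel <- function(x, ...) {
  cat(sprintf("drb_panel: %d records, %d lineages, seed %d\n",
              nrow(x$records), length(unique(x$truth$lineage)),
              x$config$seed))
  cat(sprintf("  STR sector lengths %d-%d nt\n",
              min(x$truth$str_length), max(x$truth$str_length)))
  invisible(x)
}

#' Read or write a panel configuration as YAML
#'
#' @param config A [panel_config()].
#' @param path File path.
#' @return `read_panel_config()` returns a [panel_config()].
#' @export
write_panel_config <- function(config, path) {
  stopifnot(inherits(config, "panel_config"))
  obj <- unclass(config)
  obj$lineages <- lapply(obj$lineages, unclass)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_panel_config
#' @export
read_panel_config <- function(path) {
  obj <- yaml::read_yaml(path)
  lineages <- lapply(obj$lineages, function(l) do.call(lineage_spec, l))
  panel_config(
    lineages = lineages, seed = obj$seed,
    between_lineage_exon_divergence = obj$between_lineage_exon_divergence,
    between_lineage_intron_divergence = obj$between_lineage_intron_divergence,
    str_window = unlist(obj$str_window)
  )
}
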