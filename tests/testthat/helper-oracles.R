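# Brute-force oracles and small fixture builders, independent of the
# implementation paths they check.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# per-pair column-by-column identity counting
oracle_identity <- function(m) {
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      match <- 0L
      comp <- 0L
      for (k in seq_len(ncol(m))) {
        a <- m[i, k]
        b <- m[j, k]
        if (a %in% c("-", "N") || b %in% c("-", "N")) next
        comp <- comp + 1L
        if (a == b) match <- match + 1L
      }
      vals <- c(vals, if (comp == 0L) 0 else match / comp)
    }
  }
  vals * 100
}

oracle_canonical <- function(motif) {
  u <- nchar(motif)
  min(vapply(seq_len(u), function(k) {
    paste0(substr(motif, k, u), substr(motif, 1, k - 1))
  }, character(1)))
}

# exhaustive window enumeration of maximal perfect tandem tracts, merged
# and filtered under the same declarative rules as the scanner
oracle_repeats <- function(seq, min_mono = 12, min_multi = 4, max_gap = 4,
                           min_purity = 0.85) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tracts <- list()
  for (u in 1:6) {
    for (start in seq_len(max(n - 2 * u + 1, 0))) {
      motif <- chars[start:(start + u - 1)]
      if (any(motif == "N")) next
      # primitive motif only
      prim <- TRUE
      for (d in seq_len(u - 1)) {
        if (u %% d == 0 &&
            all(motif == rep(motif[1:d], u / d))) prim <- FALSE
      }
      if (!prim) next
      # leftmost anchor: the previous char must not continue the tiling
      if (start > 1 && chars[start - 1] == motif[u] &&
          chars[start - 1] != "N") next
      end <- start + u - 1
      while (end + 1 <= n && chars[end + 1] != "N" &&
             chars[end + 1] == motif[(end + 1 - start) %% u + 1]) {
        end <- end + 1
      }
      if (end - start + 1 < 2 * u) next
      tracts[[length(tracts) + 1]] <- data.frame(
        motif = oracle_canonical(paste(motif, collapse = "")), unit_len = u,
        start = start, end = end, matched = end - start + 1, segs = 1)
    }
  }
  if (!length(tracts)) return(NULL)
  tracts <- unique(do.call(rbind, tracts))
  merged <- list()
  for (key in unique(paste(tracts$motif, tracts$unit_len))) {
    g <- tracts[paste(tracts$motif, tracts$unit_len) == key, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    cur <- g[1, ]
    for (k in seq_len(nrow(g))[-1]) {
      gap <- g$start[k] - cur$end - 1
      gap_n <- gap > 0 && any(chars[(cur$end + 1):(g$start[k] - 1)] == "N")
      if (gap >= 0 && gap <= max_gap && !gap_n) {
        cur$end <- g$end[k]
        cur$matched <- cur$matched + g$matched[k]
        cur$segs <- cur$segs + 1
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- g[k, ]
      }
    }
    merged[[length(merged) + 1]] <- cur
  }
  runs <- do.call(rbind, merged)
  runs$copies <- runs$matched / runs$unit_len
  runs$purity <- runs$matched / (runs$end - runs$start + 1)
  runs$interruptions <- runs$segs - 1
  thr <- ifelse(runs$unit_len == 1, min_mono, min_multi)
  runs <- runs[floor(runs$copies) >= thr & runs$purity >= min_purity, ,
               drop = FALSE]
  if (!nrow(runs)) return(NULL)
  len <- runs$end - runs$start + 1
  runs <- runs[order(-len, runs$start, runs$motif), , drop = FALSE]
  taken <- rep(FALSE, n)
  keep <- logical(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    span <- runs$start[k]:runs$end[k]
    if (!any(taken[span])) {
      keep[k] <- TRUE
      taken[span] <- TRUE
    }
  }
  runs <- runs[keep, , drop = FALSE]
  runs <- runs[order(runs$start), c("motif", "unit_len", "start", "end",
                                    "copies", "purity", "interruptions")]
  rownames(runs) <- NULL
  runs
}

# well-separated lineage configuration used for recovery properties
separated_config <- function(seed, n_lineages = 5, gap = 15) {
  panel_config(
    lineages = lapply(seq_len(n_lineages), function(i) {
      lineage_spec(paste0("L", i), n_alleles = 4L,
                   central_copies_mean = 15 + gap * i,
                   central_copies_sd = 1.5)
    }),
    seed = seed
  )
}

recovery_ari <- function(seed, tandem_factor = 100) {
  p <- generate_panel(separated_config(seed))
  prof <- profile_panel(p, tandem_factor = tandem_factor)
  hc <- str_hclust(distance_matrix(prof))
  truth <- setNames(p$truth$lineage, p$truth$id)
  g <- cutree(hc, k = length(unique(truth)))
  adjusted_rand(g, truth[names(g)])
}

# index (into a support_tree's support vector / the tree's internal-node
# order) of the bipartition separating `side` from the rest, or NA
match_bipartition <- function(bt, side) {
  tr <- bt$tree
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  for (i in seq_along(pp)) {
    tips <- sort(labs[pp[[i]]])
    comp <- sort(setdiff(tr$tip.label, tips))
    if (setequal(tips, side) || setequal(comp, side)) return(i)
  }
  NA_integer_
}
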