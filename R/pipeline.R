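#' Configuration for a full analysis run
#'
#' @param panel_config A [panel_config()] used to simulate the input
#'   panel (ignored when `fasta` is given).
#' @param fasta Optional path to an input FASTA of amplicon records with
#'   `id|species|lineage` headers; when given, records are read instead
#'   of simulated and must already be aligned to the scheme width (or be
#'   unaligned full amplicons of scheme width).
#' @param scheme A [sector_scheme()].
#' @param tandem_factor Tandem amplification factor for compression.
#' @param metric,mode Distance options, see [distance_matrix()].
#' @param linkage Hierarchical linkage, see [str_hclust()].
#' @param bootstrap_n Bootstrap replicates for the sector trees.
#' @param scan Named list of [find_repeats()] thresholds.
#' @param seed Integer seed propagated to every stochastic stage.
#' @param out_dir Output directory (created if needed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(panel_config = drbstr::panel_config(),
                       fasta = NULL,
                       scheme = default_sector_scheme(),
                       tandem_factor = 100L,
                       metric = "manhattan",
                       mode = "size",
                       linkage = "complete",
                       bootstrap_n = 1000L,
                       scan = list(min_mono = 12L, min_multi = 4L,
                                   max_gap = 4L, min_purity = 0.85),
                       seed = 1L,
                       out_dir = tempfile("drbstr_run_")) {
  if (!is.null(fasta) && !file.exists(fasta)) {
    stop("input FASTA does not exist: ", fasta, call. = FALSE)
  }
  structure(
    list(panel_config = panel_config, fasta = fasta, scheme = scheme,
         tandem_factor = as.integer(tandem_factor), metric = metric,
         mode = mode, linkage = linkage,
         bootstrap_n = as.integer(bootstrap_n), scan = scan,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages simulate (or load), partition, scan, compress,
#' cluster and compare, writing one artifact set per stage plus a
#' manifest of parameters and MD5 checksums. Reruns with the same
#' configuration produce identical checksums.
#'
#' @param config A [run_config()].
#' @return The run manifest (data frame: stage, file, md5), invisibly
#'   extended with attributes `results` (the in-memory stage outputs) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$out_dir, name)
  manifest <- list()
  note <- function(stage, files) {
    for (f in files) {
      manifest[[length(manifest) + 1L]] <<- data.frame(
        stage = stage, file = basename(f),
        md5 = unname(tools::md5sum(f)), stringsAsFactors = FALSE)
    }
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # 1 simulate / load
  panel <- run_stage("simulate", {
    if (!is.null(config$fasta)) {
      records <- read_fasta(config$fasta)
      aln <- setNames(records$sequence, records$id)
      p <- list(records = records,
                truth = data.frame(id = records$id,
                                   species = records$species,
                                   lineage = records$lineage,
                                   stringsAsFactors = FALSE),
                alignment = as_alignment_matrix(aln),
                config = config$panel_config)
      part0 <- partition_alignment(p$alignment, config$scheme)
      strs <- apply(part0$sectors$intron2R, 1, function(r) {
        paste(r[r != "-"], collapse = "")
      })
      p$str <- strs
      p$truth$str_length <- nchar(strs)[p$truth$id]
      structure(p, class = "drb_panel")
    } else {
      cfg <- config$panel_config
      cfg$seed <- config$seed
      generate_panel(cfg)
    }
  })
  write_fasta(panel, art("panel.fasta"))
  write_alignment_fasta(panel$alignment, art("alignment.fasta"))
  write.table(panel$truth, art("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("simulate", art(c("panel.fasta", "alignment.fasta", "truth.tsv")))

  # 2 partition + identity
  part <- run_stage("partition", partition_alignment(panel$alignment,
                                                     config$scheme))
  intron_ab <- concat_sectors(part, c("intron2A", "intron2B"))
  ident <- rbind(
    identity_report(part, c("exon2", "intron2A", "intron2B")),
    {
      st <- pairwise_identity(intron_ab)
      data.frame(sector = "intron2A+intron2B", n_pairs = st$n_pairs,
                 mean = st$mean, se = st$se, sd = st$sd,
                 stringsAsFactors = FALSE)
    }
  )
  write.table(ident, art("identity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (s in c("exon2", "intron2A", "intron2B")) {
    write_alignment_fasta(part$sectors[[s]], art(paste0(s, ".fasta")))
  }
  note("partition", art(c("identity.tsv", "exon2.fasta", "intron2A.fasta",
                          "intron2B.fasta")))

  # 3 scan
  annotations <- run_stage("scan", do.call(scan_panel, c(list(panel),
                                                         config$scan)))
  write.table(annotations, art("str_annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("scan", art("str_annotations.tsv"))

  # 4 compress + distances
  profiles <- run_stage("compress", profile_panel(panel,
                                                  config$tandem_factor))
  d_str <- distance_matrix(profiles, metric = config$metric,
                           mode = config$mode)
  write_profiles_tsv(profiles, art("profiles.tsv"))
  write_dist_csv(d_str, art("str_dist.csv"))
  write_phylip_dist(d_str, art("str_dist.phy"))
  note("compress", art(c("profiles.tsv", "str_dist.csv", "str_dist.phy")))

  # 5 cluster: STR dendrogram + sector NJ trees with bootstrap
  clust <- run_stage("cluster", {
    hc <- str_hclust(d_str, linkage = config$linkage)
    exon_bt <- bootstrap_support(part$sectors$exon2, n = config$bootstrap_n,
                                 seed = config$seed)
    intron_bt <- bootstrap_support(intron_ab, n = config$bootstrap_n,
                                   seed = config$seed)
    list(hc = hc, exon = exon_bt, intron = intron_bt)
  })
  to_newick(clust$hc, art("str_hclust.nwk"))
  to_newick(clust$exon, art("exon2_nj.nwk"))
  to_newick(clust$intron, art("intron2AB_nj.nwk"))
  note("cluster", art(c("str_hclust.nwk", "exon2_nj.nwk",
                        "intron2AB_nj.nwk")))

  # 6 compare groupings across sectors
  truth <- setNames(panel$truth$lineage, panel$truth$id)
  comp <- run_stage("compare", {
    list(str_vs_exon = compare_groupings(clust$hc, clust$exon, truth = truth),
         str_vs_intron = compare_groupings(clust$hc, clust$intron,
                                           truth = truth),
         exon_vs_intron = compare_groupings(clust$exon, clust$intron,
                                            truth = truth))
  })
  comp_tab <- do.call(rbind, lapply(names(comp), function(nm) {
    x <- comp[[nm]]
    data.frame(pair = nm, k = x$k, ari = x$ari,
               shared_bipartitions = x$shared_bipartitions,
               ari_truth_a = unname(x$ari_truth["a"]),
               ari_truth_b = unname(x$ari_truth["b"]),
               stringsAsFactors = FALSE)
  }))
  write.table(comp_tab, art("comparison.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("compare", art("comparison.tsv"))

  manifest <- do.call(rbind, manifest)
  params <- list(seed = config$seed, tandem_factor = config$tandem_factor,
                 metric = config$metric, mode = config$mode,
                 linkage = config$linkage, bootstrap_n = config$bootstrap_n,
                 scan = config$scan)
  yaml::write_yaml(list(parameters = params,
                        files = setNames(as.list(manifest$md5),
                                         manifest$file)),
                   art("manifest.yaml"))
  attr(manifest, "results") <- list(panel = panel, partition = part,
                                    identity = ident,
                                    annotations = annotations,
                                    profiles = profiles, dist = d_str,
                                    clusters = clust, comparisons = comp)
  attr(manifest, "out_dir") <- config$out_dir
  invisible(manifest)
}
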