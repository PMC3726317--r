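# Orchestration: a single configuration object, stage execution in
# dependency order, metadata headers on every output, and a run manifest
# with checksums.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list; supply overrides
#' as a nested list (e.g. from [read_pipeline_config()]) and they are merged
#' recursively. Every stage parameter named by the module functions appears
#' here under its stage block.
#'
#' @param overrides Nested list of overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = list()) {
  base <- list(
    seed = 1,
    output_dir = "teshot_run",
    simulate = list(
      n_ucos = 20, ucos_length = 1000, background_length = 1e6,
      n_libraries = 1, read_length = 60, mean_depth = 5,
      base_error_rate = 0.01, insert_size_mean = 300, insert_size_sd = 30,
      families = list(
        list(family_id = "gypsy1", te_class = "I", superfamily = "LTR/Gypsy",
             consensus_length = 5000, copy_number = 20,
             per_copy_divergence = 0.03),
        list(family_id = "copia1", te_class = "I", superfamily = "LTR/Copia",
             consensus_length = 4500, copy_number = 10,
             per_copy_divergence = 0.03),
        list(family_id = "hat1", te_class = "II", superfamily = "DNA/hAT",
             consensus_length = 3000, copy_number = 8,
             per_copy_divergence = 0.005)
      )
    ),
    prep = list(q_min = 20, equalize = FALSE, target_length = 60,
                n_replicates = 49),
    map = list(k = 13, mode = "default"),
    abundance = list(genome_size = NULL),
    diversity = list(min_depth = 7, min_base_quality = 20,
                     min_alt_support = 2, min_alt_fraction = 0.2),
    cluster = list(k = 17, min_identity = 0.9, min_overlap_fraction = 0.55,
                   cutoff = 0.01, vertex_budget = 50000)
  )
  cfg <- modifyList(base, overrides)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the fields of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: ", path)
  pipeline_config(yaml::read_yaml(path))
}

config_checksum <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL # content checksum must not depend on where it lands
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order
#' (`simulate` -> `prep` -> `map` -> `abundance`/`diversity`, plus
#' `cluster` on prepared reads). Every TSV output carries a metadata header
#' with the package version, configuration checksum and seed; re-running
#' with an identical configuration reproduces identical checksums.
#'
#' @param config A `pipeline_config`.
#' @param stages Character vector of stages to run.
#' @return A run manifest: data frame of output files with md5 checksums,
#'   with the in-memory stage results attached as attribute `results`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "prep", "map", "abundance",
                                    "diversity", "cluster")) {
  order_all <- c("simulate", "prep", "map", "abundance", "diversity",
                 "cluster")
  bad <- setdiff(stages, order_all)
  if (length(bad) > 0) stop_validation("unknown stage: ", bad[1])
  stages <- order_all[order_all %in% stages]
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(teshot = as.character(utils::packageVersion("teshot")),
               config_md5 = config_checksum(config), seed = config$seed)
  res <- list()
  out_files <- character(0)
  t0 <- Sys.time()
  log <- function(...) message(sprintf("[teshot %s] ", format(Sys.time(), "%H:%M:%S")), ...)

  need <- function(stage, dep) {
    if (is.null(res[[dep]]))
      stop_dependency("stage '", stage, "' needs outputs of stage '", dep,
                      "' (not run)")
  }

  if ("simulate" %in% stages) {
    log("simulate: building reference and reads")
    sc <- config$simulate
    specs <- lapply(sc$families, function(f) do.call(family_spec, f))
    ref <- build_reference(specs, n_ucos = sc$n_ucos,
                           ucos_length = sc$ucos_length,
                           background_length = sc$background_length,
                           seed = config$seed)
    libs <- lapply(seq_len(sc$n_libraries), function(i) {
      prof <- library_profile(read_length = sc$read_length,
                              mean_depth = sc$mean_depth,
                              base_error_rate = sc$base_error_rate,
                              insert_size_mean = sc$insert_size_mean,
                              insert_size_sd = sc$insert_size_sd,
                              library_id = sprintf("lib%d", i),
                              seed = derive_seed(config$seed, i))
      simulate_reads(ref, prof)
    })
    names(libs) <- sprintf("lib%d", seq_len(sc$n_libraries))
    f_genome <- file.path(config$output_dir, "genome.fasta")
    write_fasta(c(genome = ref$genome), f_genome)
    f_te <- file.path(config$output_dir, "te_consensus.fasta")
    write_fasta(ref$te_consensus, f_te)
    f_ucos <- file.path(config$output_dir, "ucos.fasta")
    write_fasta(ref$ucos, f_ucos)
    f_truth <- file.path(config$output_dir, "truth.tsv")
    write_truth(ref$truth, f_truth)
    f_gff <- file.path(config$output_dir, "features.gff3")
    write_feature_gff3(ref$features, f_gff)
    f_reads <- vapply(names(libs), function(nm) {
      f <- file.path(config$output_dir, paste0(nm, ".fastq"))
      write_fastq(libs[[nm]], f)
      f
    }, "")
    out_files <- c(out_files, f_genome, f_te, f_ucos, f_truth, f_gff, f_reads)
    res$simulate <- list(reference = ref, libraries = libs)
  }

  if ("prep" %in% stages) {
    need("prep", "simulate")
    log("prep: quality trimming")
    trimmed <- lapply(res$simulate$libraries, trim_reads,
                      q_min = config$prep$q_min)
    if (isTRUE(config$prep$equalize)) {
      res$prep <- list(
        libraries = trimmed,
        replicates = equalize_libraries(trimmed,
                                        target_length = config$prep$target_length,
                                        n_replicates = config$prep$n_replicates,
                                        seed = config$seed))
    } else {
      res$prep <- list(libraries = trimmed, replicates = NULL)
    }
  }

  if ("map" %in% stages) {
    need("map", "prep")
    log("map: seed-and-extend alignment")
    ref <- res$simulate$reference
    contigs <- reference_contigs(
      c(ref$te_consensus, ref$ucos),
      category = c(rep("TE", length(ref$te_consensus)),
                   rep("UCOS", length(ref$ucos))),
      te_class = c(ref$truth$families$te_class,
                   rep(NA, length(ref$ucos))),
      superfamily = c(ref$truth$families$superfamily,
                      rep(NA, length(ref$ucos))))
    idx <- build_index(contigs, k = config$map$k)
    pars <- map_params(config$map$mode)
    set.seed(derive_seed(config$seed, 999))
    res$map <- lapply(res$prep$libraries, function(lib) {
      aln <- map_reads(lib, idx, max_mismatch_rate = pars$max_mismatch_rate,
                       n_seeds = pars$n_seeds)
      list(alignments = aln,
           pileup = pileup(aln, lib, contigs,
                           min_base_quality = config$diversity$min_base_quality))
    })
    res$map_contigs <- contigs
  }

  if ("abundance" %in% stages) {
    need("abundance", "map")
    log("abundance: UCOS-normalized copy numbers")
    tabs <- lapply(names(res$map), function(nm) {
      copy_number_table(res$map[[nm]]$pileup, sample_id = nm)
    })
    names(tabs) <- names(res$map)
    gsz <- config$abundance$genome_size
    if (is.null(gsz)) gsz <- res$simulate$reference$truth$genome_size
    for (nm in names(tabs)) {
      f <- file.path(config$output_dir, paste0("abundance_", nm, ".tsv"))
      write_tsv(tabs[[nm]]$families, f,
                meta = c(meta, sample = nm,
                         ucos_baseline = tabs[[nm]]$ucos_baseline))
      out_files <- c(out_files, f)
      f2 <- file.path(config$output_dir, paste0("superfamily_", nm, ".tsv"))
      gf <- genome_fraction(tabs[[nm]], gsz)
      sf <- merge(tabs[[nm]]$superfamilies, gf, by = "superfamily")
      write_tsv(sf, f2, meta = c(meta, sample = nm, genome_size = gsz))
      out_files <- c(out_files, f2)
    }
    res$abundance <- tabs
  }

  if ("diversity" %in% stages) {
    need("diversity", "map")
    log("diversity: variable sites and partitioning")
    dv <- config$diversity
    res$diversity <- lapply(names(res$map), function(nm) {
      pu <- res$map[[nm]]$pileup
      te_ids <- res$map_contigs$contig_id[res$map_contigs$category == "TE"]
      v <- call_variant_sites(pu, min_depth = dv$min_depth,
                              min_alt_support = dv$min_alt_support,
                              min_alt_fraction = dv$min_alt_fraction,
                              contig_ids = te_ids)
      te <- res$map_contigs[res$map_contigs$category == "TE", , drop = FALSE]
      d <- nucleotide_diversity(v, te)
      f <- file.path(config$output_dir, paste0("diversity_", nm, ".tsv"))
      write_tsv(d, f, meta = c(meta, sample = nm))
      out_files <<- c(out_files, f)
      feats <- res$simulate$reference$features
      part <- NULL
      if (nrow(feats) > 0) {
        part <- partition_variants(v, feats, te)
        f2 <- file.path(config$output_dir, paste0("partition_", nm, ".tsv"))
        write_tsv(as.data.frame(part), f2, meta = c(meta, sample = nm))
        out_files <<- c(out_files, f2)
      }
      list(variants = v, diversity = d, partition = part)
    })
    names(res$diversity) <- names(res$map)
  }

  if ("cluster" %in% stages) {
    need("cluster", "prep")
    log("cluster: read-overlap graph and Louvain communities")
    cl <- config$cluster
    all_reads <- do.call(rbind, res$prep$libraries)
    g <- build_read_graph(all_reads, k = cl$k, min_identity = cl$min_identity,
                          min_overlap_fraction = cl$min_overlap_fraction,
                          vertex_budget = cl$vertex_budget,
                          seed = config$seed)
    part <- louvain_clusters(g, seed = config$seed)
    lib <- res$simulate$reference$te_consensus
    names(lib) <- res$simulate$reference$truth$families$superfamily
    rep_reads <- all_reads$sequence[g$used]
    rpt <- cluster_report(part, rep_reads, repeat_library = lib,
                          cutoff = cl$cutoff)
    f <- file.path(config$output_dir, "clusters.tsv")
    write_tsv(as.data.frame(rpt), f,
              meta = c(meta, total_reads_used = attr(rpt, "total_reads_used")))
    out_files <- c(out_files, f)
    res$cluster <- list(graph = g, partition = part, report = rpt)
  }

  log(sprintf("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  manifest <- data.frame(path = out_files,
                         md5 = unname(tools::md5sum(out_files)),
                         stringsAsFactors = FALSE)
  attr(manifest, "results") <- res
  attr(manifest, "meta") <- meta
  manifest
}
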