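#' Build a pipeline configuration
#'
#' Collects every stage parameter of the satellite mining pipeline in one
#' object. Species inputs are either FASTQ paths (`list(name=, r1=, r2=)`)
#' or simulation profiles (`list(name=, weights=, copies=, mutation_rate=,
#' indel_rate=, n_pairs=, read_length=, frag_mean=, frag_sd=, error_rate=)`)
#' drawing on a shared simulated ancestral library.
#'
#' @param species List of per-species input descriptions (see above).
#' @param consensus A `sat_consensus`, DNA string, or FASTA path. For pure
#'   simulation runs it may be `NULL`, in which case the simulated library
#'   root is used as the reference.
#' @param simulate Optional list with the shared library parameters
#'   `n_haplotypes`, `unit_length`, `divergence` (required when any species
#'   entry is a simulation profile).
#' @param pcr_clones Optional named list (species -> character vector of
#'   Sanger clone sequences) entering the pipeline as PCR-origin monomers.
#' @param subsample_n Read pairs retained per species before merging
#'   (`Inf` keeps everything; the reference analysis used 5e6).
#' @param min_overlap,max_mismatch_frac Merge parameters.
#' @param min_identity_select,min_aligned Homology-selection parameters.
#' @param min_identity_extract,length_tol Monomer-extraction parameters.
#' @param drop_singletons Discard Illumina haplotypes seen once.
#' @param cluster_threshold Greedy clustering identity (0.99).
#' @param cluster_pcr Also cluster PCR haplotypes (by default they are kept
#'   as-is, mirroring analyses where clones bypass read clustering).
#' @param indel_policy Nucleotide diversity indel policy.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `sat_config`.
#' @export
pipeline_config <- function(species, consensus = NULL, simulate = NULL,
                            pcr_clones = NULL, subsample_n = Inf,
                            min_overlap = 20L, max_mismatch_frac = 0.10,
                            min_identity_select = 0.70, min_aligned = 50L,
                            min_identity_extract = 0.60, length_tol = 0.10,
                            drop_singletons = TRUE, cluster_threshold = 0.99,
                            cluster_pcr = FALSE,
                            indel_policy = "gap_as_event", seed = 1L) {
  if (length(species) == 0L) stop_param("at least one species must be configured")
  structure(
    list(species = species, consensus = consensus, simulate = simulate,
         pcr_clones = pcr_clones, subsample_n = subsample_n,
         min_overlap = min_overlap, max_mismatch_frac = max_mismatch_frac,
         min_identity_select = min_identity_select, min_aligned = min_aligned,
         min_identity_extract = min_identity_extract, length_tol = length_tol,
         drop_singletons = drop_singletons,
         cluster_threshold = cluster_threshold, cluster_pcr = cluster_pcr,
         indel_policy = indel_policy, seed = seed),
    class = "sat_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `sat_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname read_pipeline_config
#' @param config A `sat_config`.
#' @return [write_pipeline_config()] invisibly returns `path`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full satellite mining pipeline
#'
#' For each species: obtain read pairs (FASTQ or simulation), subsample,
#' merge by overlap, select satellite-homologous merged reads against the
#' consensus, extract full monomers, and collapse to haplotypes with
#' singleton filtering. PCR clone sequences, if any, are rotation-
#' canonicalized and added with origin `"pcr"`. Haplotypes are then clustered
#' per species at the identity threshold, all representatives are pooled
#' into a global consensus-anchored alignment, and the abundance-weighted
#' minimum spanning tree is built from pairwise differences. Deterministic
#' given the master seed.
#'
#' @param config A `sat_config` (see [pipeline_config()]) or YAML path.
#' @return A list of class `sat_report`: `diversity`, `haplotypes`,
#'   `clusters`, `alignment`, `distances`, `mst`, `logos`, `funnel`,
#'   `consensus`, `config`, and (for simulation runs) `truth`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  sim <- NULL
  truth <- list()

  # Reference: explicit consensus, FASTA path, or the simulated library root.
  if (!is.null(cfg$simulate)) {
    sim <- simulate_library(
      n_haplotypes = cfg$simulate$n_haplotypes,
      unit_length = cfg$simulate$unit_length %||% 177L,
      divergence = cfg$simulate$divergence %||% 0.02,
      seed = derive_seed(cfg$seed, "library")
    )
  }
  consensus <- resolve_consensus(cfg$consensus, sim)

  funnel <- list()
  monomers <- list()
  for (sp in cfg$species) {
    name <- sp$name %||% stop_param("every species entry needs a name")
    res <- tryCatch(
      run_species(sp, cfg, consensus, sim),
      satlib_error = function(e) {
        abort(sprintf("[%s] %s", e$stage %||% "pipeline", conditionMessage(e)),
              class = class(e), stage = e$stage)
      }
    )
    funnel[[name]] <- res$funnel
    monomers[[name]] <- res$monomers
    if (!is.null(res$truth)) truth[[name]] <- res$truth
  }
  all_monomers <- dplyr::bind_rows(monomers)

  # PCR clones bypass merging/homology but share rotation canonicalization.
  if (!is.null(cfg$pcr_clones)) {
    for (name in names(cfg$pcr_clones)) {
      seqs <- canonical_rotation(cfg$pcr_clones[[name]], consensus)
      all_monomers <- dplyr::bind_rows(all_monomers, tibble(
        sequence = seqs,
        read_id = sprintf("%s_clone%03d", name, seq_along(seqs)),
        species = name, origin = "pcr", length = nchar(seqs)
      ))
    }
  }
  if (nrow(all_monomers) == 0L) {
    stop_data("no monomers were recovered in any species", stage = "mine")
  }

  haplotypes <- tally_haplotypes(all_monomers,
                                 drop_singletons = cfg$drop_singletons)
  if (nrow(haplotypes) == 0L) {
    stop_data("no haplotypes left after singleton filtering", stage = "stats")
  }
  diversity <- summarize_diversity(haplotypes, consensus = consensus,
                                   indel_policy = cfg$indel_policy)
  logos <- haplotypes |>
    dplyr::group_by(.data$species) |>
    dplyr::group_map(function(g, key) {
      alnr <- align_monomers(g$sequence, consensus = consensus)
      logo_matrix(alnr, g$count)
    }) |>
    setNames(sort(unique(haplotypes$species)))

  # Cluster Illumina haplotypes per species; PCR haplotypes join as-is
  # unless cluster_pcr.
  to_cluster <- if (cfg$cluster_pcr) haplotypes else
    dplyr::filter(haplotypes, .data$origin == "illumina")
  passthrough <- if (cfg$cluster_pcr) haplotypes[0, ] else
    dplyr::filter(haplotypes, .data$origin != "illumina")
  cl_list <- to_cluster |>
    dplyr::group_split(.data$species) |>
    purrr::map(~ greedy_cluster(.x, threshold = cfg$cluster_threshold))
  reps <- dplyr::bind_rows(purrr::map(cl_list, "clusters"))
  reps <- dplyr::bind_rows(reps, tibble(
    cluster = passthrough$haplotype, representative = passthrough$haplotype,
    sequence = passthrough$sequence, abundance = as.numeric(passthrough$count),
    n_members = 1L, species = passthrough$species, origin = passthrough$origin
  ))
  node_ids <- sprintf("n%03d_%s", seq_len(nrow(reps)), reps$species)
  reps$node <- node_ids

  aln <- align_monomers(setNames(reps$sequence, node_ids), consensus = consensus)
  dm <- pairwise_differences(aln)
  mst <- build_mst(dm, nodes = tibble(
    id = node_ids, species = reps$species, origin = reps$origin,
    abundance = reps$abundance
  ))

  funnel_tbl <- dplyr::bind_rows(funnel)
  structure(
    list(diversity = diversity, haplotypes = haplotypes,
         clusters = reps, alignment = aln, distances = dm, mst = mst,
         logos = logos, funnel = funnel_tbl, consensus = consensus,
         config = cfg, truth = if (length(truth)) dplyr::bind_rows(truth) else NULL),
    class = "sat_report"
  )
}

resolve_consensus <- function(consensus, sim) {
  if (is.null(consensus)) {
    if (is.null(sim)) stop_param("a consensus is required when not simulating")
    return(sat_consensus("SimSat01", sim$sequence[1]))
  }
  if (inherits(consensus, "sat_consensus")) return(consensus)
  if (grepl("^[ACGTN]+$", consensus)) return(sat_consensus("consensus", consensus))
  read_consensus_fasta(consensus)
}

run_species <- function(sp, cfg, consensus, sim) {
  name <- sp$name
  truth <- NULL
  if (!is.null(sp$weights)) {  # simulation profile
    if (is.null(sim)) stop_param("species simulation profiles require config$simulate")
    prof <- species_profile(name, weights = unlist(sp$weights),
                            copies = sp$copies,
                            mutation_rate = sp$mutation_rate %||% 0,
                            indel_rate = sp$indel_rate %||% 0)
    pool <- amplify_species(sim, prof,
                            seed = derive_seed(cfg$seed + species_tag(name), "amplify"))
    arr <- build_tandem_array(pool,
                              seed = derive_seed(cfg$seed + species_tag(name), "array"))
    pairs <- generate_reads(
      arr, n_pairs = sp$n_pairs %||% 500L,
      read_length = sp$read_length %||% 250L,
      frag_mean = sp$frag_mean %||% 400L, frag_sd = sp$frag_sd %||% 40,
      error_rate = sp$error_rate %||% 0,
      seed = derive_seed(cfg$seed + species_tag(name), "reads")
    )
    truth <- dplyr::mutate(arr$truth, pool_sequence = pool$sequence[match(
      .data$monomer_id, pool$monomer_id)])
  } else {
    pairs <- read_fastq_pairs(sp$r1, sp$r2)
  }
  if (nrow(pairs) == 0L) {
    stop_data(sprintf("no read pairs for species '%s'", name),
              stage = "readprep")
  }
  n_in <- nrow(pairs)
  if (is.finite(cfg$subsample_n)) {
    pairs <- subsample_pairs(pairs, cfg$subsample_n,
                             seed = derive_seed(cfg$seed + species_tag(name),
                                                "subsample"))
  }
  merged <- merge_pairs(pairs, min_overlap = cfg$min_overlap,
                        max_mismatch_frac = cfg$max_mismatch_frac)
  ok <- merged[merged$merged, , drop = FALSE]
  hits <- select_homologous(ok[, c("id", "sequence")], consensus,
                            min_identity = cfg$min_identity_select,
                            min_aligned = cfg$min_aligned)
  hom <- ok[hits$hit[match(ok$id, hits$id)], , drop = FALSE]
  mono <- extract_monomers(hom, consensus,
                           min_identity = cfg$min_identity_extract,
                           length_tol = cfg$length_tol,
                           species = name, origin = "illumina")
  list(
    monomers = mono,
    truth = truth,
    funnel = tibble(
      species = name,
      pairs_in = n_in,
      pairs_used = nrow(pairs),
      merged = nrow(ok),
      homologous = nrow(hom),
      monomers = nrow(mono),
      haplotypes = length(unique(mono$sequence))
    )
  )
}

# small stable per-species integer used to decorrelate stage seeds
species_tag <- function(name) {
  sum(utf8ToInt(name) * seq_len(nchar(name))) %% 10007L
}

#' Per-stage read accounting of a pipeline run
#'
#' The stage funnel (pairs in, pairs used, merged, homologous, monomer
#' instances, haplotypes) per species; counts are monotone non-increasing
#' along the read-processing funnel.
#'
#' @param report A `sat_report`.
#' @return Tibble, one row per species.
#' @export
funnel_counts <- function(report) report$funnel

#' Write a report bundle to a directory
#'
#' Writes the diversity TSV, haplotype table TSV, cluster table TSV, global
#' alignment FASTA, logo matrices TSV, MST GML + node table, funnel TSV and
#' the serialized configuration.
#'
#' @param report A `sat_report`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_report_bundle <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  readr::write_tsv(format_diversity(report$diversity), p("diversity.tsv"))
  readr::write_tsv(report$haplotypes, p("haplotypes.tsv"))
  readr::write_tsv(report$clusters, p("clusters.tsv"))
  readr::write_tsv(funnel_counts(report), p("funnel.tsv"))
  logos <- dplyr::bind_rows(report$logos, .id = "species")
  readr::write_tsv(logos, p("logos.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(report$alignment), p("alignment.fasta")
  )
  export_graph(report$mst, p("mst.gml"), p("mst_nodes.tsv"))
  write_pipeline_config(report$config, p("config.yaml"))
  invisible(outdir)
}
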