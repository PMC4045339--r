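#' Default end-to-end pipeline configuration
#'
#' Encodes the package's reference study conditions: the five-cell
#' community of [default_community_spec()], contigs of 6 kb mean length
#' (so even the smallest cell yields well over 20 contigs),
#' 100,000 informative Hi-C link pairs with 1% inter-cell noise
#' (the uninformative short-fragment class is not generated here — the
#' link budget is spent on the informative class the clustering
#' consumes), the 5 kb contig-size / 5-contact matrix filters, and MCL
#' at inflation 1.1 scored with 100,000 size-weighted sampled pairs.
#'
#' @param seed global seed fanned out to per-stage seeds.
#' @return Nested configuration list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    community = list(divergence = 0.005),
    contigs = list(mean_contig_len = 6000, min_contig_len = 1000,
                   coassembly_prob = 0.5),
    hic = list(n_pairs = 100000, frac_fragment = 0, noise_rate = 0.01,
               p_cross_replicon = 0.2, site_anchoring = 0.9),
    filter = list(mapq_min = 0, require_full = FALSE, insert_min = 0),
    matrix = list(min_contacts = 5, min_contig_len = 5000),
    mcl = list(inflation = 1.1),
    evaluation = list(n_pairs = 100000, labels = "truth"),
    association = list(exclude_below = 1000)
  ), class = "pipeline_config")
}

required_config_sections <- c("seed", "community", "contigs", "hic",
                              "filter", "matrix", "mcl", "evaluation")

#' Validate a pipeline configuration
#'
#' @param config a configuration list.
#' @return The config, invisibly; errors name any missing section.
#' @export
validate_config <- function(config) {
  missing <- setdiff(required_config_sections, names(config))
  if (length(missing) > 0)
    stop_param("pipeline config is missing section(s): %s",
               paste(missing, collapse = ", "))
  invisible(config)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file path (`.yaml`/`.yml` needs the yaml package;
#'   `.json` uses jsonlite).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- unclass(default_pipeline_config(seed = cfg$seed %||% 1))
  for (sec in intersect(names(cfg), names(base))) {
    if (is.list(base[[sec]])) {
      base[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    } else {
      base[[sec]] <- cfg[[sec]]
    }
  }
  validate_config(structure(base, class = "pipeline_config"))
}

#' Run the full deconvolution pipeline
#'
#' Executes simulate community -> digest -> fragment to contigs ->
#' simulate Hi-C links -> link filter -> association matrix -> matrix
#' filter + normalization -> MCL clustering -> quality evaluation and
#' replicon association, each stage seeded deterministically from the
#' global seed so identical configs produce identical results. When
#' `out_dir` is given, every artifact is written in the package's plain
#' text formats together with a checksum manifest.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @param out_dir optional output directory (created if needed).
#' @return A list of class `pipeline_result` with the community, contig
#'   set, link table, association matrix, cluster solution, quality
#'   reports (species and strain level), replicon association table, and
#'   the config.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL) {
  validate_config(config)
  seed <- config$seed
  community <- generate_community(
    default_community_spec(divergence = config$community$divergence %||%
                             0.005),
    seed = derive_seed(seed, "community"))
  rmaps <- digest_community(community)
  contigs <- fragment_to_contigs(
    community,
    mean_contig_len = config$contigs$mean_contig_len,
    min_contig_len = config$contigs$min_contig_len,
    coassembly_prob = config$contigs$coassembly_prob %||% 0.5,
    seed = derive_seed(seed, "contigs"))
  sp <- sim_params(n_pairs = config$hic$n_pairs,
                   frac_fragment = config$hic$frac_fragment %||% 0,
                   noise_rate = config$hic$noise_rate %||% 0,
                   p_cross_replicon = config$hic$p_cross_replicon %||% 0.2,
                   site_anchoring = config$hic$site_anchoring %||% 0.9)
  links <- simulate_hic_pairs(community, sp, rmaps = rmaps,
                              seed = derive_seed(seed, "hic"))
  fp <- filter_params(mapq_min = config$filter$mapq_min %||% 0,
                      require_full = config$filter$require_full %||% FALSE,
                      insert_min = config$filter$insert_min %||% 0)
  links_f <- filter_links(links, fp, ref_info = community)
  clinks <- liftover_links(links_f, contigs)
  mat <- build_association_matrix(clinks, contigs)
  matf <- normalize_assoc(filter_assoc(
    mat, min_contacts = config$matrix$min_contacts,
    min_contig_len = config$matrix$min_contig_len))
  solution <- mcl_cluster(matf, mcl_params(
    inflation = config$mcl$inflation))
  universe <- mat$ids[mat$lengths >= config$matrix$min_contig_len]
  solution <- complete_solution(solution, universe)
  labels <- truth_labels(contigs)
  labels_run <- labels[labels$contig_id %in% universe, , drop = FALSE]
  q_species <- sample_pair_quality(
    solution, labels_run, n_pairs = config$evaluation$n_pairs,
    level = "species", seed = derive_seed(seed, "eval_species"))
  q_strain <- sample_pair_quality(
    solution, labels_run, n_pairs = config$evaluation$n_pairs,
    level = "strain", seed = derive_seed(seed, "eval_strain"))
  assoc_tab <- replicon_association_table(
    links, community,
    exclude_below = config$association$exclude_below %||% 1000)
  result <- structure(list(community = community, contigs = contigs,
                           links = links, matrix = matf,
                           solution = solution,
                           quality_species = q_species,
                           quality_strain = q_strain,
                           replicon_assoc = assoc_tab,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$community)
  print(x$solution)
  print(x$quality_species)
  print(x$replicon_assoc)
  invisible(x)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  write_community_fasta(result$community, pth("community.fasta"))
  write_ground_truth(result$community, pth("ground_truth.json"))
  write_links(result$links, pth("links.tsv"), truth = TRUE)
  utils::write.table(result$contigs$contigs, pth("contigs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_assoc(result$matrix, pth("matrix.tsv"), pth("contig_lengths.tsv"))
  write_clusters(result$solution, pth("clusters.tsv"))
  q <- result$quality_species
  jsonlite::write_json(
    list(species = unclass(result$quality_species)[
           c("TP", "FP", "FN", "TN", "TPR", "FPR", "PPV", "NPV",
             "n_pairs")],
         strain = unclass(result$quality_strain)[
           c("TP", "FP", "FN", "TN", "TPR", "FPR", "PPV", "NPV",
             "n_pairs")],
         n_clusters = result$solution$n_clusters,
         within_cell_rate = result$replicon_assoc$within_cell_rate),
    pth("quality.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(result$replicon_assoc$table,
                     pth("replicon_association.tsv"), sep = "\t",
                     quote = FALSE)
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   pth("manifest.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, pth("manifest.json"), digits = NA)
  invisible(out_dir)
}
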