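# End-to-end pipeline: clustering -> core/variable partition -> Pn/Ps,
# distances and tree -> CRISPR detect/orient/match/immunity -> biogeography,
# with a manifest sufficient to re-run.

#' Pipeline configuration
#'
#' Collects every stage threshold with the published settings as defaults:
#' bit-score-ratio screen 0.3, MCL inflation 2.0, strict >50% spacer
#' identity, PAM motif CCN read 5' of the protospacer, seed region 8 nt,
#' and a minimum of 5 members for Pn/Ps alignments.
#'
#' @param ratio_threshold bit-score-ratio screen
#' @param inflation MCL inflation
#' @param id_threshold strict whole-spacer identity threshold
#' @param pam_motif,pam_side PAM configuration
#' @param seed_len seed region length (nt)
#' @param min_anchor minimum exact match run for a reported spacer match
#' @param min_pnps_members minimum cluster size for Pn/Ps
#' @param require_pam require a PAM for immunity calls
#' @param rescue run the six-frame rescue step
#' @param fallback_orfs call ORFs naively for genomes without CDS features
#' @param reference_repeat repeat used to orient arrays (NULL: each array's
#'   own consensus, i.e. forward)
#' @param seed integer seed recorded in the manifest
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(ratio_threshold = 0.3, inflation = 2,
                            id_threshold = 0.5, pam_motif = "CCN",
                            pam_side = "5prime", seed_len = 8L,
                            min_anchor = 12L,
                            min_pnps_members = 5L, require_pam = TRUE,
                            rescue = TRUE, fallback_orfs = FALSE,
                            reference_repeat = NULL, seed = 1L) {
  if (ratio_threshold < 0 || ratio_threshold > 1)
    stop("ratio_threshold must lie in [0, 1]")
  if (id_threshold < 0 || id_threshold > 1)
    stop("id_threshold must lie in [0, 1]")
  if (inflation <= 1) stop("inflation must exceed 1")
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes clustering, the core/variable partition, per-cluster Pn/Ps, the
#' concatenated-core Jukes-Cantor neighbor-joining tree, CRISPR array
#' detection and orientation, spacer matching with PAM annotation, immunity
#' calls against the observed infection matrix, and the biogeographic
#' summaries; writes all result tables plus a manifest to `out_dir`.
#'
#' @param viruses named list of annotated virus [genome_record()]
#' @param hosts named list of host [genome_record()]
#' @param sample_sheet data.frame mapping ids to locations
#' @param infection optional infection-outcome data.frame
#' @param out_dir output directory
#' @param config a [pipeline_config()]
#' @return object of class `sirv_run` (all stage results), invisibly
#' @export
run_pipeline <- function(viruses, hosts, sample_sheet, infection = NULL,
                         out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  params <- alignment_params()

  pg <- stage("pangenome", pangenome(
    viruses, params, ratio_threshold = config$ratio_threshold,
    inflation = config$inflation, rescue = config$rescue,
    fallback_orfs = config$fallback_orfs))

  pnps <- stage("pnps", pangenome_pnps(pg, config$min_pnps_members, params))

  tree <- stage("core_tree", {
    rows <- concat_core_alignment(pg, params)
    nj_tree(jc_matrix(rows))
  })

  arrays <- stage("crispr_detect",
                  unlist(lapply(hosts, detect_arrays), recursive = FALSE))
  spacers <- stage("crispr_orient", {
    sp <- lapply(arrays, function(a)
      orient_spacers(a, config$reference_repeat %||% a$consensus))
    res <- do.call(rbind, sp)
    if (is.null(res)) stop("no CRISPR arrays detected in any host")
    rownames(res) <- NULL
    res
  })
  matches <- stage("crispr_match", match_all_spacers(
    spacers, viruses, config$id_threshold, config$pam_motif,
    config$pam_side, config$seed_len, config$min_anchor))
  immunity <- stage("immunity", call_immunity(
    matches, names(hosts), names(viruses), infection,
    config$id_threshold, config$require_pam))

  fractions <- stage("biogeo_fractions",
                     match_fractions(spacers, matches, sample_sheet,
                                     config$id_threshold))
  hist <- stage("biogeo_identity",
                identity_distribution(matches, sample_sheet,
                                      config$id_threshold))
  partition <- stage("biogeo_partition", {
    if (nrow(matches)) region_partition(matches, viruses, pg) else NULL
  })

  tables <- list(
    clusters = pg$membership,
    presence_absence = data.frame(cluster_id = rownames(pg$pa),
                                  as.data.frame(pg$pa),
                                  stringsAsFactors = FALSE),
    core_stats = pg$core_stats,
    pnps = pnps,
    spacers = data.frame(spacers[, c("spacer_id", "host_id", "array_id",
                                     "index", "sequence", "orientation")],
                         stringsAsFactors = FALSE),
    matches = transform(matches, start = start + 1L),  # 1-based inclusive
    immunity = as.data.frame(immunity),
    fractions_by_location = fractions$by_location,
    fractions_by_location_virus = fractions$by_location_virus,
    identity_hist = hist)
  if (!is.null(partition)) tables$region_partition <- partition
  paths <- write_tables(tables, out_dir,
                        config = unclass(config), seed = config$seed)
  ape::write.tree(tree, file.path(out_dir, "core_tree.nwk"))

  invisible(structure(list(pangenome = pg, pnps = pnps, tree = tree,
                           arrays = arrays, spacers = spacers,
                           matches = matches, immunity = immunity,
                           fractions = fractions, identity_hist = hist,
                           region_partition = partition,
                           out_dir = out_dir, config = config),
                      class = "sirv_run"))
}

#' @export
print.sirv_run <- function(x, ...) {
  cat("<sirv_run>\n")
  print(x$pangenome)
  cat(sprintf("  %d spacers, %d reported matches; results in %s\n",
              nrow(x$spacers), nrow(x$matches), x$out_dir))
  invisible(x)
}

#' One-command synthetic demo
#'
#' Simulates a population under the default study conditions (or a supplied
#' configuration), writes the fixture, and runs the full pipeline on it.
#'
#' @param seed integer seed (drives both the simulation and the pipeline)
#' @param out_dir output directory; fixture goes to `out_dir/fixture`
#' @param sim a [sim_config()] (its seed is overridden by `seed`)
#' @param config a [pipeline_config()]
#' @return list with `population` and `run`
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("sirvpop_demo"),
                     sim = sim_config(), config = pipeline_config()) {
  sim$seed <- as.integer(seed)
  config$seed <- as.integer(seed)
  pop <- simulate_population(sim)
  emit_fixture(pop, file.path(out_dir, "fixture"))
  run <- run_pipeline(pop$viruses, pop$hosts, pop$sample_sheet,
                      pop$infection, file.path(out_dir, "results"), config)
  list(population = pop, run = run)
}

#' Reproduce the published real-data numbers
#'
#' Runs the genome statistics, pangenome counts, core Pn/Ps and spacer
#' matching stages on locally downloaded accession data. The package never
#' downloads: `data_dir` must contain `viruses.fasta` and `features.gff`
#' covering the ten SIRV genomes (GenBank KY744228-KY744235, NC_004086.1,
#' NC_004087.1), and optionally `hosts.fasta` plus `samples.tsv` for the
#' CRISPR biogeography stage.
#'
#' @param data_dir directory with the downloaded accession files
#' @param config a [pipeline_config()]
#' @return list with mean_genome_length, mean_gc_percent, cluster counts
#'   pre/post rescue, core count, core Pn/Ps table, and (when host data are
#'   present) per-location match fractions
#' @export
reproduce_published <- function(data_dir, config = pipeline_config()) {
  vf <- file.path(data_dir, "viruses.fasta")
  gf <- file.path(data_dir, "features.gff")
  if (!file.exists(vf) || !file.exists(gf))
    stop("accession data not present under '", data_dir,
         "': expected viruses.fasta and features.gff ",
         "(downloaded GenBank accessions; this package never downloads)")
  viruses <- read_gff(gf, read_fasta(vf))
  lens <- vapply(viruses, function(g) nchar(g$sequence), numeric(1))
  gcs <- vapply(viruses, function(g) gc_content(g$sequence), numeric(1))
  pg <- pangenome(viruses, ratio_threshold = config$ratio_threshold,
                  inflation = config$inflation, rescue = config$rescue)
  core_pre <- sum(apply(pg$pa_pre_rescue != "absent", 1, all))
  pnps <- pangenome_pnps(pg, config$min_pnps_members)
  out <- list(mean_genome_length = mean(lens),
              mean_gc_percent = 100 * mean(gcs),
              n_clusters = length(pg$clusters),
              n_core_clusters = sum(pg$status == "core"),
              n_core_clusters_pre_rescue = core_pre,
              core_pnps = pnps[pnps$status == "core", , drop = FALSE],
              pangenome = pg)
  hf <- file.path(data_dir, "hosts.fasta")
  sf <- file.path(data_dir, "samples.tsv")
  if (file.exists(hf) && file.exists(sf)) {
    hosts <- read_fasta(hf)
    ss <- read_sample_sheet(sf)
    arrays <- unlist(lapply(hosts, detect_arrays), recursive = FALSE)
    spacers <- do.call(rbind, lapply(arrays, function(a)
      orient_spacers(a, config$reference_repeat %||% a$consensus)))
    matches <- match_all_spacers(spacers, viruses, config$id_threshold,
                                 config$pam_motif, config$pam_side,
                                 config$seed_len, config$min_anchor)
    out$fractions <- match_fractions(spacers, matches, ss,
                                     config$id_threshold)
  }
  out
}
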