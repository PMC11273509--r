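#' Default pipeline configuration
#'
#' A single nested list holding every stage parameter with its standard
#' default, suitable for serialising to YAML. Stage toggles switch whole
#' stages on or off; `seed` feeds every stochastic stage.
#'
#' @param seed global integer seed.
#' @param out_dir run directory (created if needed).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "panel", "classify", "relate", "assign")`.
#' @param sim a [sim_config()] for the simulate stage.
#' @param ... named overrides for stage parameter lists `panel`,
#'   `classify`, `relate`, `assign` (see the function defaults).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("crosskin_run_"),
                            stages = c("simulate", "panel", "classify",
                                       "relate", "assign"),
                            sim = sim_config(seed = seed), ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir, stages = stages,
    sim = sim,
    panel = list(slack = 5, min_allele_depth = 6, maf_min = 0.25,
                 het_min = 0.2, miss_max = 0.7, hwe_p_min = 0.01,
                 miss_max_final = 0.8),
    relate = list(times_two = TRUE, tree = TRUE, max_tree_samples = 150),
    assign = list(params = likelihood_sim_params(),
                  accepted_error_rate = 0.05))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic-herd pipeline
#'
#' Orchestrates simulate -> panel selection -> generation classification
#' -> relatedness -> parentage assignment on a simulated herd, writing
#' each stage's outputs (VCF, pedigree TSV, panel TSVs, ratio tables,
#' assignment tables, newick tree) into the run directory together with a
#' JSON provenance manifest recording parameters and the md5 checksum of
#' every file. Reruns with the same configuration reproduce identical
#' checksums for all deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  files <- character(0)
  results <- list()
  note <- function(stage, params, fs) {
    manifest$stages[[stage]] <<- list(
      params = params,
      files = as.list(tools::md5sum(fs)))
    files <<- c(files, fs)
  }
  stage_on <- function(s) s %in% config$stages

  if (!stage_on("simulate"))
    stop("pipeline currently starts from the simulate stage")
  herd <- simulate_herd(config$sim, observe = TRUE)
  vcf_path <- file.path(config$out_dir, "herd.vcf")
  ped_path <- file.path(config$out_dir, "pedigree.tsv")
  write_vcf(herd$genotypes, vcf_path)
  write_pedigree(herd$pedigree, ped_path)
  note("simulate", unclass(config$sim), c(vcf_path, ped_path))
  results$herd <- herd
  ped <- herd$pedigree
  sires <- ped$id[ped$role == "sire"]
  dams <- ped$id[ped$role == "dam"]
  offspring <- ped$id[ped$role == "offspring"]
  gm <- herd$genotypes

  if (stage_on("panel")) {
    pc <- config$panel
    gen_panel <- select_generation_panel(gm, sires, dams, slack = pc$slack,
                                         min_allele_depth = pc$min_allele_depth)
    par_panel <- select_parentage_panel(gm, sires, maf_min = pc$maf_min,
                                        het_min = pc$het_min,
                                        miss_max = pc$miss_max,
                                        hwe_p_min = pc$hwe_p_min,
                                        min_allele_depth = pc$min_allele_depth,
                                        miss_max_final = pc$miss_max_final)
    gp_path <- file.path(config$out_dir, "panel_generation.tsv")
    pp_path <- file.path(config$out_dir, "panel_parentage.tsv")
    write_panel(gen_panel, gp_path)
    write_panel(par_panel, pp_path)
    note("panel", pc, c(gp_path, pp_path))
    results$gen_panel <- gen_panel
    results$par_panel <- par_panel
  }

  if (stage_on("classify")) {
    if (is.null(results$gen_panel)) stop("classify stage requires panel stage")
    if (!nrow(results$gen_panel)) stop("empty generation panel")
    ratios <- compute_ratios(gm, results$gen_panel, offspring)
    labelled <- classify_generation(ratios)
    ev <- evaluate_against_truth(labelled, ped)
    cls_path <- file.path(config$out_dir, "generation_labels.tsv")
    utils::write.table(labelled, cls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("classify", list(), cls_path)
    manifest$stages$classify$accuracy_generation <- ev$accuracy_generation
    results$labels <- labelled
    results$evaluation <- ev
  }

  if (stage_on("relate")) {
    if (is.null(results$par_panel)) stop("relate stage requires panel stage")
    rc <- config$relate
    kin <- centered_ibs_kinship(gm, times_two = rc$times_two)
    kin_path <- file.path(config$out_dir, "kinship.tsv")
    utils::write.table(round(kin, 6), kin_path, sep = "\t", quote = FALSE)
    fs <- kin_path
    if (isTRUE(rc$tree)) {
      tree_ids <- c(sires, dams,
                    utils::head(offspring,
                                max(0, rc$max_tree_samples -
                                      length(sires) - length(dams))))
      d <- p_distance(subset_gm(gm, samples = tree_ids))
      tree <- neighbor_joining(d)
      tree_path <- file.path(config$out_dir, "nj_tree.nwk")
      ape::write.tree(tree, tree_path)
      fs <- c(fs, tree_path)
      results$tree <- tree
    }
    note("relate", rc, fs)
    results$kinship <- kin
  }

  if (stage_on("assign")) {
    if (is.null(results$par_panel)) stop("assign stage requires panel stage")
    if (nrow(results$par_panel) < 2) stop("parentage panel too small")
    ac <- config$assign
    f1_ids <- ped$id[!is.na(ped$generation) & ped$generation == "F1"]
    lik <- assign_likelihood(gm, results$par_panel, f1_ids, sires,
                             params = ac$params, seed = config$seed)
    apis <- assign_apis(gm, results$par_panel, f1_ids, sires, dams,
                        accepted_error_rate = ac$accepted_error_rate)
    excl <- assign_exclusion(gm, results$par_panel, f1_ids, sires, dams)
    cons <- consensus_assignments(lik, apis)
    lik_path <- file.path(config$out_dir, "assign_likelihood.tsv")
    apis_path <- file.path(config$out_dir, "assign_apis.tsv")
    excl_path <- file.path(config$out_dir, "assign_exclusion.tsv")
    venn_path <- file.path(config$out_dir, "assign_venn.json")
    utils::write.table(lik, lik_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(apis, apis_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(excl$best, excl_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(as.list(cons$venn), venn_path, auto_unbox = TRUE)
    note("assign", list(accepted_error_rate = ac$accepted_error_rate),
         c(lik_path, apis_path, excl_path, venn_path))
    results$likelihood <- lik
    results$apis <- apis
    results$exclusion <- excl
    results$consensus <- cons
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(manifest = manifest, results = results,
                 out_dir = config$out_dir))
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML file of stage parameters and merges it over
#' [pipeline_config()] defaults. Recognised top-level keys: `seed`,
#' `out_dir`, `stages`, `sim`, `panel`, `relate`, `assign`.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- if (is.null(y$sim)) list() else y$sim
  if (!is.null(y$seed) && is.null(sim_args$seed)) sim_args$seed <- y$seed
  cfg <- pipeline_config(
    seed = if (is.null(y$seed)) 1L else y$seed,
    out_dir = if (is.null(y$out_dir)) tempfile("crosskin_run_") else y$out_dir,
    stages = if (is.null(y$stages)) c("simulate", "panel", "classify",
                                      "relate", "assign") else y$stages,
    sim = do.call(sim_config, sim_args))
  for (nm in intersect(names(y), c("panel", "relate")))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], y[[nm]])
  if (!is.null(y$assign)) {
    if (!is.null(y$assign$accepted_error_rate))
      cfg$assign$accepted_error_rate <- y$assign$accepted_error_rate
    if (!is.null(y$assign$params))
      cfg$assign$params <- do.call(likelihood_sim_params, y$assign$params)
  }
  cfg
}
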