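#' Default planted family design for the synthetic study
#'
#' Three shared families present in all species and three clade-specific
#' families private to the ingroup, two subfamilies each, with the default
#' identity structure (within > 0.9, between < 0.3, domain length 400).
#'
#' @return list of [family_spec()]s.
#' @export
default_family_specs <- function() {
  list(family_spec("FAMA"), family_spec("FAMB"), family_spec("FAMC"),
       family_spec("FAMD", clade_specific = TRUE),
       family_spec("FAME", clade_specific = TRUE),
       family_spec("FAMF", clade_specific = TRUE))
}

#' Build a pipeline configuration
#'
#' Every default mirrors the published analysis values: E-value threshold
#' 1e-10, protein length bounds 350/650, identity threshold 0.55, shortlist
#' size 36, expression design 5 wild + 6 cultivated samples. All defaults
#' are echoed into the run report for provenance.
#'
#' @param mode "synthetic" (simulate the inputs; `seed` mandatory) or
#'   "files" (load them from `files`).
#' @param seed integer master seed (synthetic mode).
#' @param search a [search_config()].
#' @param tau strict identity threshold for subfamily partitioning.
#' @param ingroup ingroup species labels (defaults to the design's ingroup).
#' @param focal_species focal species for class counts and the shortlist.
#' @param top_k shortlist size.
#' @param family_specs list of [family_spec()]s (synthetic mode).
#' @param decoy_count decoy sequences (synthetic mode).
#' @param n_wild,n_cultivated expression sample counts (synthetic mode).
#' @param design a [species_design()] (synthetic mode).
#' @param files named list of paths for files mode: `proteomes` (vector of
#'   per-species FASTAs with `species|gene` headers), `seed_alignment`
#'   (FASTA), `expression` (TSV), plus `group_map` (named list
#'   sample -> group).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"), seed = NULL,
                            search = search_config(), tau = 0.55,
                            ingroup = NULL, focal_species = NULL,
                            top_k = 36, family_specs = default_family_specs(),
                            decoy_count = 20, n_wild = 5, n_cultivated = 6,
                            design = species_design(), files = NULL) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(seed)) {
    stop("seed is mandatory in synthetic mode")
  }
  if (is.null(ingroup)) ingroup <- design$ingroup_ids
  if (is.null(focal_species)) focal_species <- ingroup[1]
  if (mode == "files") {
    paths <- unlist(files[c("proteomes", "seed_alignment", "expression")])
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("input file does not exist: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(mode = mode, seed = seed, search = search, tau = tau,
                 ingroup = ingroup, focal_species = focal_species,
                 top_k = top_k, family_specs = family_specs,
                 decoy_count = decoy_count, n_wild = n_wild,
                 n_cultivated = n_cultivated, design = design, files = files),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields (mode, seed, tau, ingroup, focal_species, top_k,
#' search thresholds, file paths) are read from the YAML and merged into
#' [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  search_args <- y$search %||% list()
  args <- list(mode = y$mode %||% "synthetic", seed = y$seed,
               search = do.call(search_config, search_args),
               tau = y$tau %||% 0.55, ingroup = unlist(y$ingroup),
               focal_species = y$focal_species, top_k = y$top_k %||% 36,
               decoy_count = y$decoy_count %||% 20, n_wild = y$n_wild %||% 5,
               n_cultivated = y$n_cultivated %||% 6, files = y$files)
  do.call(pipeline_config, args[!vapply(args, is.null, TRUE)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full candidate-discovery pipeline
#'
#' Stages, in order: mine (profile scan + significance/length screen),
#' cluster (identity matrix, neighbor-joining tree, subfamily partition),
#' specificity (clade-specific calls and focal class counts), rank
#' (expression means, specific-vs-shared rank-sum test, candidate
#' shortlist). Fully deterministic given the config and seeds. Intermediate
#' artifacts and a machine-readable JSON report are written to `outdir`
#' when given.
#'
#' @param config a [pipeline_config()], or a path to a YAML config.
#' @param outdir optional output directory.
#' @return run report: list with per-stage counts, echoed parameters, class
#'   counts, rank-sum result, the shortlist, and warnings.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  warnings <- character(0)

  # ---- inputs
  if (config$mode == "synthetic") {
    pipeline_log("input", "simulating synthetic bundle (seed ", config$seed, ")")
    bundle <- simulate_gene_families(config$design, config$family_specs,
                                     decoy_count = config$decoy_count,
                                     seed = config$seed)
    bundle$expression <- simulate_expression(bundle$truth,
                                             n_wild = config$n_wild,
                                             n_cultivated = config$n_cultivated,
                                             seed = config$seed + 1L)
    seed_aln <- bundle$seed_alignment
  } else {
    pipeline_log("input", "loading input files")
    proteomes <- list()
    for (f in config$files$proteomes) {
      aa <- Biostrings::readAAStringSet(f)
      parsed <- parse_fasta_headers(names(aa))
      for (sp in unique(parsed$species)) {
        sel <- parsed$species == sp
        proteomes[[sp]] <- c(proteomes[[sp]],
                             stats::setNames(as.character(aa)[sel],
                                             parsed$gene[sel]))
      }
    }
    aa <- Biostrings::readAAStringSet(config$files$seed_alignment)
    seed_aln <- stats::setNames(as.character(aa), names(aa))
    df <- read.table(config$files$expression, header = TRUE, sep = "\t",
                     check.names = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df$gene
    groups <- stats::setNames(as.character(unlist(config$files$group_map)),
                              names(config$files$group_map))
    bundle <- list(proteomes = proteomes,
                   expression = structure(list(values = vals, groups = groups),
                                          class = "expression_table"))
  }
  n_proteins <- sum(lengths(bundle$proteomes))

  # ---- stage 1: mine
  pipeline_log("mine", "scanning ", n_proteins, " proteins")
  profile <- build_profile(seed_aln)
  hits <- scan_proteome(profile, bundle$proteomes, config$search)
  kept <- filter_hits(hits, config$search)
  pipeline_log("mine", nrow(kept), " of ", nrow(hits),
               " scanned proteins pass the screen")
  if (nrow(kept) < 2) stop("stage mine failed: fewer than 2 superfamily members")

  # ---- stage 2: cluster
  pipeline_log("cluster", "identity matrix and NJ tree for ", nrow(kept), " genes")
  species_map <- stats::setNames(kept$species, kept$gene)
  all_seqs <- unlist(unname(lapply(bundle$proteomes, as.list)), recursive = FALSE)
  member_seqs <- stats::setNames(
    vapply(kept$gene, function(g) all_seqs[[g]], ""), kept$gene)
  idmat <- build_identity_matrix(member_seqs)
  tree <- neighbor_joining(1 - idmat)
  assignment <- partition_subfamilies(tree, idmat, tau = config$tau,
                                      species = species_map)
  n_subfam <- length(unique(assignment$genes$subfamily_id))
  pipeline_log("cluster", n_subfam, " subfamilies")

  # ---- stage 3: specificity
  calls <- call_clade_specific(assignment, config$ingroup)
  class_counts <- specificity_summary(calls, assignment, config$focal_species)
  pipeline_log("specificity", sum(calls$specific), " clade-specific and ",
               sum(!calls$specific), " shared subfamilies")

  # ---- stage 4: rank
  means <- group_mean_expression(bundle$expression)
  rank_sum <- tryCatch(
    compare_specific_vs_nonspecific(means, calls, assignment),
    error = function(e) {
      warnings <<- c(warnings, conditionMessage(e))
      NULL
    })
  shortlist <- withCallingHandlers(
    rank_candidates(calls, means, assignment, top_k = config$top_k,
                    focal_species = config$focal_species),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  pipeline_log("rank", "shortlist of ", nrow(shortlist), " candidates")

  report <- list(
    stages = list(
      mine = list(n_proteins = n_proteins, n_scanned = nrow(hits),
                  n_kept = nrow(kept)),
      cluster = list(n_genes = nrow(kept), n_subfamilies = n_subfam),
      specificity = list(n_specific_subfamilies = sum(calls$specific),
                         n_shared_subfamilies = sum(!calls$specific)),
      rank = list(n_candidates = sum(calls$specific[
        match(assignment$genes$subfamily_id, calls$subfamily_id)]),
        shortlist_size = nrow(shortlist))),
    parameters = list(mode = config$mode, seed = config$seed,
                      e_max = config$search$e_max,
                      len_lo = config$search$len_lo,
                      len_hi = config$search$len_hi,
                      n_shuffles = config$search$n_shuffles,
                      tau = config$tau, top_k = config$top_k,
                      ingroup = config$ingroup,
                      focal_species = config$focal_species),
    class_counts = unclass(class_counts)[c(
      "n_specific_subfamilies", "n_shared_subfamilies",
      "n_specific_genes_focal", "n_shared_genes_focal", "focal_total_genes")],
    rank_sum = rank_sum,
    shortlist = as.data.frame(shortlist),
    warnings = warnings)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_hits_tsv(kept, file.path(outdir, "hits.tsv"))
    write.table(assignment$genes, file.path(outdir, "subfamilies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(calls), file.path(outdir, "specificity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report$shortlist, file.path(outdir, "shortlist.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ape::write.tree(tree, file.path(outdir, "members_nj.nwk"))
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"),
               file.path(outdir, "report.json"))
  }
  report
}
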