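#' Assemble a pipeline run configuration
#'
#' Nested list of per-stage parameters with sensible desk-scale defaults.
#' Every stochastic stage receives its own seed derived from the global seed
#' and the stage name, so toggling one stage never shifts the randomness of
#' another.
#'
#' @param seed global seed.
#' @param outdir output directory.
#' @param stages stages to run, in dependency order, among `"simulate"`,
#'   `"categories"`, `"cluster"`, `"overlap"`, `"decode"`.
#' @param stimulus list of [stim_config()] overrides.
#' @param tuning list of [tuning_config()] overrides (plus `n_rep`,
#'   `screen_alpha`).
#' @param categories list: `n_lowlevel` (members per low-level category),
#'   `k_shape`, `n_templates`.
#' @param cluster list: `k_range`, `lambda`, `d_max`, `n_consensus`,
#'   `link_threshold`, `n_iter`.
#' @param overlap list: `n_perm`.
#' @param decode list: `categories` (named list of object-id vectors or
#'   `NULL` for all semantic categories), `n_runs`, `n_loops`, `n_vectors`.
#' @return a `RunConfig` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("popcode_run_"),
                            stages = c("simulate", "categories", "cluster",
                                       "overlap", "decode"),
                            stimulus = list(), tuning = list(),
                            categories = list(), cluster = list(),
                            overlap = list(), decode = list()) {
  defaults <- list(
    seed = seed, outdir = outdir, stages = stages,
    stimulus = stimulus,
    tuning = utils::modifyList(list(n_rep = 7L, screen_alpha = 0.005,
                                    weight_sd = 5, baseline = 10,
                                    semantic_gain = list()), tuning),
    categories = utils::modifyList(list(n_lowlevel = 15L, k_shape = 15L,
                                        n_templates = 60L), categories),
    cluster = utils::modifyList(list(k_range = 2:20, lambda = 0.8,
                                     d_max = 6L, n_consensus = 10L,
                                     link_threshold = 0.5, n_iter = 300L),
                                cluster),
    overlap = utils::modifyList(list(n_perm = 1000L), overlap),
    decode = utils::modifyList(list(categories = NULL, n_runs = 20L,
                                    n_loops = 30L, n_vectors = 7L,
                                    n_null = 20L), decode))
  structure(defaults, class = "RunConfig")
}

#' Load a run configuration from JSON or YAML
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file whose top-level
#'   keys match the arguments of [pipeline_config()].
#' @return a `RunConfig`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: `simulate` (stimuli,
#' image properties, spiking population, responsiveness screening),
#' `categories` (semantic, low-level and shape-based schemes), `cluster`
#' (population matrix, similarity, hierarchical clustering, BIC/AIC k-means,
#' consensus D-MST forest), `overlap` (k-means and twin-aware forest
#' permutation tests) and `decode` (FLD decoding of original and pruned
#' categories). Writes artifacts to `config$outdir` plus a machine-readable
#' `report.json`; the same config and seed reproduce the report exactly.
#'
#' @param config a `RunConfig` from [pipeline_config()] or [load_config()].
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env()
  report <- list(seed = config$seed, stages = config$stages)
  need <- function(what, stage) {
    if (is.null(st[[what]])) {
      stop(sprintf("stage '%s' requires '%s' from an earlier stage", stage,
                   what), call. = FALSE)
    }
    st[[what]]
  }

  for (stage in config$stages) {
    message("stage: ", stage)
    sseed <- derive_seed(config$seed, stage)
    if (stage == "simulate") {
      st$stimset <- generate_stimulus_set(
        do.call(stim_config, config$stimulus), seed = sseed)
      st$props <- property_table(st$stimset)
      tc <- config$tuning
      sg <- unlist(tc$semantic_gain)
      st$tuning <- tuning_config(
        n_neurons = if (is.null(tc$n_neurons)) 94L else tc$n_neurons,
        weight_sd = tc$weight_sd, baseline = tc$baseline,
        semantic_gain = if (length(sg)) sg else numeric(0),
        seed = derive_seed(sseed, "tuning"))
      ds_all <- simulate_population(st$stimset, st$tuning, n_rep = tc$n_rep,
                                    seed = derive_seed(sseed, "population"),
                                    props = st$props)
      st$ds <- suppressMessages(screen_responsive(ds_all, tc$screen_alpha))
      write_stimulus_set(st$stimset, file.path(config$outdir, "stimuli"))
      utils::write.table(st$props, file.path(config$outdir, "properties.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_response_table(st$ds, file.path(config$outdir, "responses.tsv"))
      report$simulate <- list(
        n_images = length(st$stimset$images),
        n_twin_sets = length(unique(st$stimset$objects$twin_set_id)),
        n_neurons_simulated = st$tuning$n_neurons,
        n_neurons_responsive = length(st$ds$neuron_ids))
    } else if (stage == "categories") {
      stimset <- need("stimset", stage)
      props <- need("props", stage)
      st$schemes <- list(
        semantic = semantic_scheme(stimset),
        low_level = build_lowlevel_categories(
          props, n = min(config$categories$n_lowlevel,
                         floor(nrow(props) / 2))),
        shape_based = build_shape_categories(
          extract_c2_features(stimset,
                              shapefeat_config(
                                n_templates = config$categories$n_templates),
                              seed = derive_seed(sseed, "templates")),
          k = config$categories$k_shape, seed = derive_seed(sseed, "kmeans")))
      jsonlite::write_json(
        lapply(st$schemes, function(s) s$categories),
        file.path(config$outdir, "categories.json"))
      report$categories <- lapply(st$schemes, function(s)
        vapply(s$categories, length, 1L))
    } else if (stage == "cluster") {
      ds <- need("ds", stage)
      st$pm <- suppressWarnings(normalize_responses(ds))
      st$sm <- similarity_matrix(st$pm)
      animate <- need("stimset", stage)$objects$is_animate
      animate[is.na(animate)] <- FALSE
      hb <- hierarchical_branch_test(st$sm, animate)
      kr <- config$cluster$k_range
      kr <- kr[kr < nrow(st$pm)]
      ks <- select_k(st$pm, kr, seed = derive_seed(sseed, "selectk"))
      st$kmeans <- with_seed(derive_seed(sseed, "kmeans"),
                             stats::kmeans(st$pm, ks$k_bic, nstart = 10))
      runs <- lapply(seq_len(config$cluster$n_consensus), function(r) {
        build_forest(st$sm$d, dmst_params(
          lambda = config$cluster$lambda, d_max = config$cluster$d_max,
          n_iter = config$cluster$n_iter, n_restarts = 1L,
          seed = derive_seed(sseed, paste0("forest", r))))
      })
      st$forest <- consensus_forest(runs, config$cluster$link_threshold)
      utils::write.table(st$sm$d, file.path(config$outdir, "dissimilarity.tsv"),
                         sep = "\t", quote = FALSE)
      writeLines(hb$newick, file.path(config$outdir, "dendrogram.nwk"))
      write_forest(st$forest, file.path(config$outdir, "forest.tsv"))
      report$cluster <- list(
        branch_chisq_p = hb$p, k_bic = ks$k_bic, k_aic = ks$k_aic,
        n_trees = sum(st$forest$parent == 0))
    } else if (stage == "overlap") {
      schemes <- need("schemes", stage)
      km <- need("kmeans", stage)
      forest <- need("forest", stage)
      twin <- stats::setNames(need("stimset", stage)$objects$twin_set_id,
                              need("stimset", stage)$objects$object_id)
      clusters <- split(rownames(st$pm), km$cluster)
      st$overlap <- lapply(names(schemes), function(nm) {
        list(kmeans = kmeans_overlap_test(
               clusters, schemes[[nm]], n_perm = config$overlap$n_perm,
               seed = derive_seed(sseed, paste0("km_", nm))),
             dmst = suppressWarnings(dmst_overlap_test(
               forest, schemes[[nm]], twin,
               n_perm = config$overlap$n_perm,
               seed = derive_seed(sseed, paste0("dmst_", nm)))))
      })
      names(st$overlap) <- names(schemes)
      for (nm in names(st$overlap)) {
        write_overlap_table(st$overlap[[nm]]$dmst,
                            file.path(config$outdir,
                                      paste0("overlap_dmst_", nm, ".tsv")))
        write_overlap_table(st$overlap[[nm]]$kmeans,
                            file.path(config$outdir,
                                      paste0("overlap_kmeans_", nm, ".tsv")))
      }
      report$overlap <- lapply(st$overlap, function(o) {
        list(n_significant_kmeans = sum(o$kmeans$significant),
             dmst = o$dmst[, c("category", "overlap", "p_twin", "p_object")])
      })
    } else if (stage == "decode") {
      ds <- need("ds", stage)
      schemes <- need("schemes", stage)
      stimset <- need("stimset", stage)
      twin <- stats::setNames(stimset$objects$twin_set_id,
                              stimset$objects$object_id)
      cats <- config$decode$categories
      if (is.null(cats)) cats <- schemes$semantic$categories
      dc <- config$decode
      rows <- list()
      for (nm in names(cats)) {
        members <- intersect(cats[[nm]], ds$object_ids)
        if (length(members) < 2) next
        res <- run_fld_task(ds, members, n_vectors = dc$n_vectors,
                            n_loops = dc$n_loops, n_runs = dc$n_runs,
                            n_null = dc$n_null,
                            seed = derive_seed(sseed, paste0("fld_", nm)))
        conflicting <- schemes[setdiff(names(schemes), "semantic")]
        pr <- prune_category(members, conflicting, twin,
                             universe = ds$object_ids,
                             seed = derive_seed(sseed, paste0("prune_", nm)))
        pruned_perf <- if (!pr$too_small &&
                           length(pr$negative) >= 2) {
          sub <- run_fld_task(ds, pr$positive, negative = pr$negative,
                              n_vectors = dc$n_vectors,
                              n_loops = dc$n_loops, n_runs = dc$n_runs,
                              n_null = dc$n_null,
                              seed = derive_seed(sseed, paste0("fldp_", nm)))
          sub$performance
        } else NA_real_
        rows[[nm]] <- data.frame(
          category = nm, n_objects = length(members),
          performance = res$performance, sd = res$sd,
          null_mean = res$null_mean, null_sd = res$null_sd, p = res$p,
          pruned_size = length(pr$positive),
          pruned_performance = pruned_perf)
      }
      st$decoding <- do.call(rbind, rows)
      utils::write.table(st$decoding, file.path(config$outdir, "decoding.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$decode <- st$decoding
    } else {
      stop("unknown stage: ", stage, call. = FALSE)
    }
  }
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `categories`, `cluster`, `overlap`, `decode`
#' run the pipeline up to (and including) that stage; `all` runs
#' everything. Flags: `--config <path>` (JSON/YAML), `--seed <int>`,
#' `--outdir <path>`, `--log-level <quiet|info>`.
#'
#' @param args character vector (defaults to the command line).
#' @return the pipeline report, invisibly.
#' @export
popcode_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages_all <- c("simulate", "categories", "cluster", "overlap", "decode")
  if (length(args) == 0) {
    stop("usage: popcode <", paste(c(stages_all, "all"), collapse = "|"),
         "> [--config f] [--seed n] [--outdir d] [--log-level l]",
         call. = FALSE)
  }
  cmd <- args[1]
  opt <- list(config = NULL, seed = NULL, outdir = NULL, log_level = "info")
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opt)) stop("unknown flag: ", args[i], call. = FALSE)
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  config <- if (!is.null(opt$config)) load_config(opt$config) else
    pipeline_config()
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  if (!is.null(opt$outdir)) config$outdir <- opt$outdir
  config$stages <- if (cmd == "all") stages_all else {
    if (!cmd %in% stages_all) stop("unknown subcommand: ", cmd, call. = FALSE)
    stages_all[seq_len(match(cmd, stages_all))]
  }
  run <- function() run_pipeline(config)
  if (identical(opt$log_level, "quiet")) suppressMessages(run()) else run()
}
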