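# End-to-end orchestration: simulate -> preprocess -> infer -> topology ->
# roles -> stability -> crosslinks -> mrm, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with explicit per-stage seeds, so
#' each output file is reproducible bit-for-bit from the configuration
#' alone. With `simulate = TRUE` the input tables are generated by
#' [make_synthetic_dataset()]; otherwise `count_paths` (named per kingdom)
#' and `labels_path` must point at existing files.
#'
#' @param simulate Generate synthetic inputs (default TRUE).
#' @param count_paths Named character vector of count TSV paths per kingdom
#'   (ignored when simulating).
#' @param labels_path Sidecar label table path (ignored when simulating).
#' @param plant_path,env_path Optional plant table / environment TSV paths.
#' @param n_samples,n_taxa_per_kingdom,mean_depth Synthetic-data scale.
#' @param min_prevalence Prevalence filter threshold (occurrence in fewer
#'   samples removes a taxon; default 5).
#' @param r_threshold Collinearity threshold for environmental variables.
#' @param pseudocount CLR pseudocount.
#' @param n_penalties,penalty_ratio Penalty path settings.
#' @param stars_subsamples,stars_fraction,stars_beta StARS settings.
#' @param stability_replicates,stability_max_fraction Robustness settings.
#' @param null_replicates Erdos-Renyi ensemble size.
#' @param mrm_permutations MRM permutation count.
#' @param seed_simulate,seed_rarefy,seed_infer,seed_modules,seed_stability,seed_null,seed_mrm
#'   Stage seeds.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE,
                            count_paths = NULL,
                            labels_path = NULL,
                            plant_path = NULL,
                            env_path = NULL,
                            n_samples = 30L,
                            n_taxa_per_kingdom = c(fungi = 15, bacteria = 15,
                                                   archaea = 10),
                            mean_depth = 2000,
                            min_prevalence = 5L,
                            r_threshold = 0.7,
                            pseudocount = 1,
                            n_penalties = 20L,
                            penalty_ratio = 0.01,
                            stars_subsamples = 20L,
                            stars_fraction = 0.8,
                            stars_beta = 0.05,
                            stability_replicates = 20L,
                            stability_max_fraction = 0.5,
                            null_replicates = 199L,
                            mrm_permutations = 199L,
                            seed_simulate = 1L, seed_rarefy = 2L,
                            seed_infer = 3L, seed_modules = 4L,
                            seed_stability = 5L, seed_null = 6L,
                            seed_mrm = 7L) {
  cfg <- as.list(environment())
  if (!is_fraction(cfg$stars_beta) || !is_fraction(cfg$stars_fraction) ||
      cfg$stars_fraction <= 0 || cfg$stars_fraction >= 1)
    stop2("invalid StARS settings")
  if (!is_count(cfg$min_prevalence) || cfg$min_prevalence < 1)
    stop2("min_prevalence must be >= 1")
  if (!cfg$simulate) {
    if (is.null(cfg$count_paths) || is.null(names(cfg$count_paths)))
      stop2("count_paths must be a named vector when simulate = FALSE")
    missing <- cfg$count_paths[!file.exists(cfg$count_paths)]
    if (length(missing) > 0)
      stop2("missing input path(s): ", paste(missing, collapse = ", "))
    for (p in c(cfg$labels_path, cfg$plant_path, cfg$env_path))
      if (!is.null(p) && !file.exists(p)) stop2("missing input path: ", p)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a key=value text file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values are parsed as numbers or logicals where possible; the keys are
#' the arguments of [pipeline_config()] (vector-valued keys use
#' comma-separated `name:value` pairs, e.g.
#' `n_taxa_per_kingdom = fungi:15, bacteria:15`).
#'
#' @param path Configuration file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop2("config not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad) > 0) stop2(path, ": cannot parse line ", bad[1])
  args <- list()
  for (m in kv) {
    key <- trimws(m[2]); val <- trimws(m[3])
    parsed <- if (grepl(":", val, fixed = TRUE)) {
      parts <- strsplit(strsplit(val, ",", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
      stats::setNames(as.numeric(trimws(vapply(parts, `[`, "", 2))),
                      trimws(vapply(parts, `[`, "", 1)))
    } else if (grepl(",", val, fixed = TRUE)) {
      trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (toupper(val) %in% c("TRUE", "FALSE")) {
      as.logical(val)
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else val
    args[[key]] <- parsed
  }
  do.call(pipeline_config, args)
}

pipeline_stages <- c("simulate", "preprocess", "infer", "topology", "roles",
                     "stability", "crosslinks", "mrm")

#' Run the multi-kingdom analysis pipeline
#'
#' Executes the requested stages in order, writing every artifact under
#' `out_dir` and a `manifest.json` recording package version, configuration,
#' per-stage seeds and an md5 checksum of each output file. Identical
#' configuration implies identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisible list with the in-memory results (`dataset`, `merged`,
#'   `network`, `topology`, `roles`, `stability`, `crosslinks`, `mrm`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- pipeline_stages
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown) > 0)
    stop2("unknown stage(s): ", paste(unknown, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  files <- character()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e)
      stop2("stage '", stage, "' failed: ", conditionMessage(e)))
  }
  out <- function(name) file.path(out_dir, name)
  reg <- function(path) { files <<- c(files, path); path }

  # --- simulate ---------------------------------------------------------
  run_stage("simulate", function() {
    log_stage("simulate", "seed ", config$seed_simulate)
    ds <- make_synthetic_dataset(
      spec = precision_spec(config$n_taxa_per_kingdom,
                            seed = config$seed_simulate),
      n_samples = config$n_samples, mean_depth = config$mean_depth,
      seed = config$seed_simulate)
    for (k in names(ds$counts))
      write_count_table(ds$counts[[k]], reg(out(sprintf("counts_%s.tsv", k))))
    utils::write.table(ds$labels, reg(out("labels.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(taxon_id = rownames(ds$plant_table), ds$plant_table,
                 check.names = FALSE),
      reg(out("plant.tsv")), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = rownames(ds$environment), ds$environment,
                 check.names = FALSE),
      reg(out("environment.tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.csv(ds$truth, reg(out("truth.csv")), row.names = FALSE)
    res$dataset <<- ds
  })

  # --- preprocess -------------------------------------------------------
  run_stage("preprocess", function() {
    tables <- if (!is.null(res$dataset)) {
      res$dataset$counts
    } else if (config$simulate) {
      ks <- names(config$n_taxa_per_kingdom)
      stats::setNames(lapply(ks, function(k)
        read_count_table(out(sprintf("counts_%s.tsv", k)), kingdom = k)), ks)
    } else {
      stats::setNames(lapply(names(config$count_paths), function(k)
        read_count_table(config$count_paths[[k]],
                         labels_path = config$labels_path, kingdom = k)),
        names(config$count_paths))
    }
    log_stage("preprocess", "rarefy to min depth, prevalence >= ",
              config$min_prevalence)
    tables <- lapply(tables, rarefy, seed = config$seed_rarefy)
    tables <- lapply(tables, prevalence_filter,
                     min_samples = config$min_prevalence)
    plant <- NULL
    plant_path <- if (!is.null(res$dataset)) out("plant.tsv") else
      config$plant_path
    if (config$simulate || !is.null(config$plant_path)) {
      pt <- read_count_table(plant_path %||% out("plant.tsv"),
                             kingdom = "plants")
      plant <- pt$counts
    }
    merged <- merge_kingdoms(unname(tables), plant_table = plant)
    res$merged <<- merged
    for (k in names(merged$blocks))
      write_count_table(merged$blocks[[k]],
                        reg(out(sprintf("filtered_%s.tsv", k))))
    # environmental collinearity filter
    env_path <- if (config$simulate) out("environment.tsv") else
      config$env_path
    if (!is.null(env_path) && file.exists(env_path)) {
      envdf <- utils::read.delim(env_path, check.names = FALSE)
      env <- as.matrix(envdf[, -1, drop = FALSE])
      rownames(env) <- envdf[[1]]
      retained <- withCallingHandlers(
        collinearity_filter(env, config$r_threshold),
        warning = function(w) invokeRestart("muffleWarning"))
      res$environment <<- attr(retained, "env")
      writeLines(retained, reg(out("retained_variables.txt")))
      log_stage("preprocess", length(retained), " of ", ncol(env),
                " environmental variables retained (|r| <= ",
                config$r_threshold, ")")
    }
  })

  # --- infer ------------------------------------------------------------
  run_stage("infer", function() {
    if (is.null(res$merged)) stop2("run the preprocess stage first")
    log_stage("infer", "StARS over ", config$n_penalties, " penalties, ",
              config$stars_subsamples, " subsamples, beta ",
              config$stars_beta)
    latent <- clr_transform(res$merged, config$pseudocount)
    net <- infer_network(res$merged, pseudocount = config$pseudocount,
                         penalties = lambda_path(latent,
                                                 config$n_penalties,
                                                 config$penalty_ratio),
                         n_subsamples = config$stars_subsamples,
                         subsample_fraction = config$stars_fraction,
                         beta = config$stars_beta,
                         seed = config$seed_infer)
    res$network <<- net
    write_network(net, reg(out("network.graphml")), "graphml")
    write_network(net, reg(out("edges.csv")), "edge_csv")
  })

  # --- topology ---------------------------------------------------------
  run_stage("topology", function() {
    if (is.null(res$network)) stop2("run the infer stage first")
    ts <- topology_summary(res$network, seed = config$seed_modules)
    res$topology <<- ts
    jsonlite::write_json(unclass(ts), reg(out("topology.json")),
                         auto_unbox = TRUE, digits = NA)
    cents <- node_centralities(res$network)
    utils::write.csv(cents, reg(out("centralities.csv")), row.names = FALSE)
    log_stage("topology", "N=", ts$node_count, " E=", ts$edge_count)
  })

  # --- roles ------------------------------------------------------------
  run_stage("roles", function() {
    if (is.null(res$network)) stop2("run the infer stage first")
    roles <- node_roles(res$network, seed = config$seed_modules)
    res$roles <<- roles
    utils::write.csv(as.data.frame(roles), reg(out("node_roles.csv")),
                     row.names = FALSE)
    log_stage("roles", sum(roles$role == "connector"), " connectors")
  })

  # --- stability --------------------------------------------------------
  run_stage("stability", function() {
    if (is.null(res$network)) stop2("run the infer stage first")
    curve <- robustness_curve(res$network,
                              max_fraction = config$stability_max_fraction,
                              n_replicates = config$stability_replicates,
                              seed = config$seed_stability)
    res$stability <<- curve
    utils::write.csv(as.data.frame(curve), reg(out("stability_curve.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(slope = attr(curve, "slope"),
           r_squared = attr(curve, "r_squared"),
           n_replicates = attr(curve, "n_replicates"),
           seed = attr(curve, "seed")),
      reg(out("stability.json")), auto_unbox = TRUE, digits = NA)
    log_stage("stability", "slope ", signif(attr(curve, "slope"), 3))
  })

  # --- crosslinks -------------------------------------------------------
  run_stage("crosslinks", function() {
    if (is.null(res$network)) stop2("run the infer stage first")
    dec <- decompose_links(res$network)
    utils::write.csv(as.data.frame(dec), reg(out("link_decomposition.csv")),
                     row.names = FALSE)
    g <- as_sn_graph(res$network)
    kl <- igraph::vertex_attr(g, "kingdom")
    counts <- table(kl)
    focal <- names(counts)[which.max(counts == max(counts))]
    focal <- if ("fungi" %in% names(counts)) "fungi" else names(counts)[1]
    exp_p <- expected_link_proportions(
      stats::setNames(as.integer(counts), names(counts)), focal)
    cross <- dec[!dec$within &
                   (dec$kingdom_a == focal | dec$kingdom_b == focal), ]
    partner <- ifelse(cross$kingdom_a == focal, cross$kingdom_b,
                      cross$kingdom_a)
    obs_p <- stats::setNames(rep(0, length(exp_p)), names(exp_p))
    if (nrow(cross) > 0 && sum(cross$edges) > 0)
      obs_p[partner] <- cross$edges / sum(cross$edges)
    dev <- preference_deviates(obs_p, exp_p)
    pref <- data.frame(kingdom = names(exp_p),
                       expected = as.numeric(exp_p),
                       observed = as.numeric(obs_p[names(exp_p)]),
                       deviate = as.numeric(dev[names(exp_p)]))
    utils::write.csv(pref, reg(out("link_preference.csv")),
                     row.names = FALSE)
    res$crosslinks <<- list(decomposition = dec, preference = pref)
    # negative-edge enrichment of the focal kingdom's cross links
    if (any(igraph::edge_attr(g, "sign") < 0)) {
      nullr <- er_null_negative_proportion(
        res$network,
        group_a = function(v) v$kingdom == focal,
        group_b = function(v) v$kingdom != focal,
        n_random = config$null_replicates, seed = config$seed_null)
      res$crosslinks$null <<- nullr
      jsonlite::write_json(unclass(nullr), reg(out("null_model.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  })

  # --- mrm --------------------------------------------------------------
  run_stage("mrm", function() {
    if (is.null(res$merged)) stop2("run the preprocess stage first")
    blocks <- res$merged$blocks
    kingdoms <- setdiff(names(blocks), "plants")
    dists <- lapply(blocks[kingdoms], bray_curtis)
    preds1 <- list()
    if (!is.null(res$environment)) {
      env <- scale(res$environment)
      preds1$environment <- new_distance_matrix(
        as.matrix(stats::dist(env)), rownames(env), "euclidean")
    }
    if ("plants" %in% names(blocks))
      preds1$plants <- jaccard(blocks$plants)
    fits <- list()
    for (k in kingdoms) {
      p1 <- preds1
      if (length(p1) == 0) next
      m1 <- mrm(dists[[k]], p1, n_permutations = config$mrm_permutations,
                seed = config$seed_mrm)
      p2 <- c(p1, dists[setdiff(kingdoms, k)])
      m2 <- mrm(dists[[k]], p2, n_permutations = config$mrm_permutations,
                seed = config$seed_mrm)
      fits[[k]] <- list(mrm1 = m1, mrm2 = m2)
    }
    res$mrm <<- fits
    jsonlite::write_json(
      lapply(fits, function(f) list(
        mrm1 = list(r_squared = f$mrm1$r_squared,
                    coefficients = f$mrm1$coefficients),
        mrm2 = list(r_squared = f$mrm2$r_squared,
                    coefficients = f$mrm2$coefficients))),
      reg(out("mrm.json")), auto_unbox = TRUE, digits = NA, dataframe = "rows")
    log_stage("mrm", length(fits), " response kingdoms fit")
  })

  # --- manifest ---------------------------------------------------------
  files <- unique(files[file.exists(files)])
  manifest <- list(
    package = "kingdomnet",
    version = as.character(utils::packageVersion("kingdomnet")),
    stages = stages,
    config = config[setdiff(names(config), c("count_paths"))],
    checksums = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  res$manifest <- manifest
  invisible(res)
}
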