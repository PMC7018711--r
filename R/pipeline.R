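#' Read a continuous trait table
#'
#' CSV with columns `taxon` and `skull_length_mm`; values are log10
#' transformed for rate analyses.
#'
#' @param path CSV file path.
#' @param log10_transform transform to log10 (default TRUE).
#' @return named numeric vector.
#' @export
read_trait_csv <- function(path, log10_transform = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  val_col <- setdiff(names(df), "taxon")[1]
  if (!"taxon" %in% names(df) || is.na(val_col))
    stop("trait CSV must have columns taxon and a value column")
  v <- df[[val_col]]
  if (log10_transform) {
    if (any(v <= 0)) stop("trait values must be positive for log10")
    v <- log10(v)
  }
  stats::setNames(v, df$taxon)
}

#' Build a run configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Either `scenario =
#' TRUE` (synthetic data with known truth) or input file paths must be
#' given. Every stochastic stage derives its seed deterministically from
#' `seed` and the stage name.
#'
#' @param output_dir directory for stage outputs and the manifest.
#' @param seed global integer seed.
#' @param scenario generate synthetic inputs instead of reading files.
#' @param n_taxa,n_char scenario size.
#' @param nexus,ranges_csv,trees_newick,outgroups_csv,trait_csv input
#'   paths (ignored when `scenario = TRUE`).
#' @param stages character vector of stages to run, in dependency order;
#'   any subset of `c("distances", "ordination", "disparity", "tests",
#'   "timescale", "discrete_rates", "trait_rates")`.
#' @param metric distance metric for the distances stage.
#' @param correction PCoA correction.
#' @param bin_scheme,bin_width time-bin controls.
#' @param n_boot,n_perm bootstrap and permutation counts.
#' @param dating_method,n_trees,min_length,resolution time-scaling
#'   controls.
#' @param mcmc_iterations,mcmc_burn_in,mcmc_thinning,ss_stones,ss_iters
#'   variable-rates sampler controls.
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1, scenario = FALSE,
                       n_taxa = 40, n_char = 60,
                       nexus = NULL, ranges_csv = NULL, trees_newick = NULL,
                       outgroups_csv = NULL, trait_csv = NULL,
                       stages = c("distances", "ordination", "disparity",
                                  "tests", "timescale", "discrete_rates",
                                  "trait_rates"),
                       metric = "mord", correction = "none",
                       bin_scheme = "equal", bin_width = 10,
                       n_boot = 500, n_perm = 999,
                       dating_method = "mbl", n_trees = 5, min_length = 1,
                       resolution = 500,
                       mcmc_iterations = 20000, mcmc_burn_in = 4000,
                       mcmc_thinning = 20, ss_stones = 20, ss_iters = 400) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML or key=value file
#'
#' @param path configuration file; YAML when the yaml package is
#'   installed, otherwise simple `key: value` lines are parsed directly.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    lines <- grep("^\\s*[^#]", readLines(path), value = TRUE)
    kv <- strsplit(lines, ":", fixed = TRUE)
    stats::setNames(lapply(kv, function(x) utils::type.convert(
      trimws(paste(x[-1], collapse = ":")), as.is = TRUE)),
      vapply(kv, function(x) trimws(x[1]), ""))
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Deterministic per-stage seed
#'
#' Derives a stage-specific seed (below 2^31) from the global seed and the
#' stage name, so every stochastic stage of [run_pipeline()] is
#' reproducible in isolation.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 +
              sum(utf8ToInt(stage)) * 131) %% 2147483587)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order: distances ->
#' ordination/disparity/tests, timescale -> discrete rates, timescale ->
#' trait rates. Outputs are written as CSV/Newick files in
#' `config$output_dir` together with `manifest.csv` (file, md5, stage) and
#' the serialised configuration; a failing stage leaves completed outputs
#' in place and is recorded in `failure_report.csv`, and stages depending
#' on it are skipped.
#'
#' @param config a [run_config()], or a path readable by
#'   [read_run_config()].
#' @return list: `outputs` (per-stage result objects), `manifest` (data
#'   frame), `failures` (data frame, empty when everything succeeded).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  .validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_file <- function(...) file.path(config$output_dir, ...)

  outputs <- list(); files <- character(0); stage_of <- character(0)
  failures <- data.frame(stage = character(0), error = character(0),
                         stringsAsFactors = FALSE)
  done <- character(0)
  emit <- function(path, stage) {
    files <<- c(files, path); stage_of <<- c(stage_of, stage)
  }
  fail <- function(stage, e) {
    failures <<- rbind(failures,
                       data.frame(stage = stage,
                                  error = conditionMessage(e),
                                  stringsAsFactors = FALSE))
  }
  needs <- function(stage, deps) {
    if (!stage %in% config$stages) return(FALSE)
    missing_dep <- setdiff(deps, done)
    if (length(missing_dep)) {
      failures <<- rbind(failures, data.frame(
        stage = stage,
        error = paste("skipped: depends on", paste(missing_dep, collapse = ", ")),
        stringsAsFactors = FALSE))
      return(FALSE)
    }
    TRUE
  }

  ## ---- inputs ----
  inputs <- tryCatch(.load_inputs(config), error = function(e) e)
  if (inherits(inputs, "error")) {
    fail("inputs", inputs)
    .write_pipeline_reports(config, files, stage_of, failures, out_file)
    return(list(outputs = outputs,
                manifest = .read_manifest(out_file("manifest.csv")),
                failures = failures))
  }
  bins <- inputs$bins
  utils::write.csv(data.frame(bin = bins$label, old = bins$old,
                              young = bins$young),
                   out_file("bins.csv"), row.names = FALSE)
  emit(out_file("bins.csv"), "inputs")
  done <- c(done, "inputs")

  ## ---- distances ----
  if (needs("distances", "inputs")) {
    res <- tryCatch({
      d <- morph_distance_matrix(inputs$matrix, config$metric)
      tr <- trim_distance_matrix(d)
      write_distance_csv(tr$dist, out_file("distances_D.csv"),
                         out_file("distances_C.csv"))
      utils::write.csv(tr$log, out_file("distances_trim_log.csv"),
                       row.names = FALSE)
      emit(out_file("distances_D.csv"), "distances")
      emit(out_file("distances_C.csv"), "distances")
      emit(out_file("distances_trim_log.csv"), "distances")
      tr
    }, error = function(e) e)
    if (inherits(res, "error")) fail("distances", res)
    else { outputs$distances <- res; done <- c(done, "distances") }
  }

  ## ---- ordination ----
  if (needs("ordination", "distances")) {
    res <- tryCatch({
      ord <- morph_pcoa(outputs$distances$dist, config$correction)
      write_ordination_csv(ord, out_file("ordination_coords.csv"))
      utils::write.csv(
        data.frame(axis = seq_along(ord$eigenvalues),
                   eigenvalue = ord$eigenvalues,
                   pct_variance = variance_explained(ord)),
        out_file("ordination_variance.csv"), row.names = FALSE)
      emit(out_file("ordination_coords.csv"), "ordination")
      emit(out_file("ordination_variance.csv"), "ordination")
      ord
    }, error = function(e) e)
    if (inherits(res, "error")) fail("ordination", res)
    else { outputs$ordination <- res; done <- c(done, "ordination") }
  }

  ## ---- disparity ----
  if (needs("disparity", "distances")) {
    res <- tryCatch({
      s1 <- disparity_through_time(outputs$distances$dist, inputs$ranges,
                                   bins, weighted = FALSE,
                                   n_boot = config$n_boot,
                                   seed = stage_seed(config$seed, "disparity"))
      s2 <- disparity_through_time(outputs$distances$dist, inputs$ranges,
                                   bins, weighted = TRUE,
                                   n_boot = config$n_boot,
                                   seed = stage_seed(config$seed, "disparity_w"))
      utils::write.csv(s1, out_file("disparity_pairwise.csv"),
                       row.names = FALSE)
      utils::write.csv(s2, out_file("disparity_weighted.csv"),
                       row.names = FALSE)
      emit(out_file("disparity_pairwise.csv"), "disparity")
      emit(out_file("disparity_weighted.csv"), "disparity")
      list(pairwise = s1, weighted = s2)
    }, error = function(e) e)
    if (inherits(res, "error")) fail("disparity", res)
    else { outputs$disparity <- res; done <- c(done, "disparity") }
  }

  ## ---- tests ----
  if (needs("tests", "distances")) {
    res <- tryCatch({
      membership <- assign_taxa_to_bins(inputs$ranges, bins)
      membership <- lapply(membership, intersect,
                           y = outputs$distances$dist$taxa)
      perma <- suppressWarnings(
        pairwise_permanova(outputs$distances$dist, membership,
                           n_perm = config$n_perm,
                           seed = stage_seed(config$seed, "tests")))
      tt <- pairwise_disparity_ttests(outputs$distances$dist, membership)
      utils::write.csv(perma, out_file("tests_permanova.csv"),
                       row.names = FALSE)
      utils::write.csv(tt, out_file("tests_ttests.csv"), row.names = FALSE)
      emit(out_file("tests_permanova.csv"), "tests")
      emit(out_file("tests_ttests.csv"), "tests")
      list(permanova = perma, ttests = tt)
    }, error = function(e) e)
    if (inherits(res, "error")) fail("tests", res)
    else { outputs$tests <- res; done <- c(done, "tests") }
  }

  ## ---- timescale ----
  if (needs("timescale", "inputs")) {
    res <- tryCatch({
      dated <- date_tree_sample(inputs$trees, inputs$ranges,
                                method = config$dating_method,
                                outgroup_ages = inputs$outgroup_ages,
                                n_keep = config$n_trees,
                                min_length = config$min_length,
                                resolution = config$resolution,
                                seed = stage_seed(config$seed, "timescale"))
      if (!length(dated)) stop("no tree could be dated")
      write_dated_trees(dated, out_file("dated_trees.nwk"),
                        out_file("dated_trees_root_ages.csv"))
      emit(out_file("dated_trees.nwk"), "timescale")
      emit(out_file("dated_trees_root_ages.csv"), "timescale")
      dated
    }, error = function(e) e)
    if (inherits(res, "error")) fail("timescale", res)
    else { outputs$timescale <- res; done <- c(done, "timescale") }
  }

  ## ---- discrete rates ----
  if (needs("discrete_rates", "timescale")) {
    res <- tryCatch({
      dr <- discrete_rates_analysis(inputs$matrix, outputs$timescale, bins)
      per_tree <- do.call(rbind, lapply(seq_along(dr$reports), function(i)
        cbind(tree = i, dr$reports[[i]])))
      utils::write.csv(per_tree, out_file("discrete_rates_bins.csv"),
                       row.names = FALSE)
      utils::write.csv(dr$summary$mean, out_file("discrete_rates_mean.csv"),
                       row.names = FALSE)
      emit(out_file("discrete_rates_bins.csv"), "discrete_rates")
      emit(out_file("discrete_rates_mean.csv"), "discrete_rates")
      dr
    }, error = function(e) e)
    if (inherits(res, "error")) fail("discrete_rates", res)
    else { outputs$discrete_rates <- res; done <- c(done, "discrete_rates") }
  }

  ## ---- trait rates ----
  if (needs("trait_rates", "timescale")) {
    res <- tryCatch({
      tree1 <- outputs$timescale[[1]]
      trait <- inputs$trait[tree1$tip.label]
      cfg <- vr_config(iterations = config$mcmc_iterations,
                       burn_in = config$mcmc_burn_in,
                       thinning = config$mcmc_thinning)
      sd0 <- stage_seed(config$seed, "trait_rates")
      post <- vr_mcmc(tree1, trait, cfg, seed = sd0)
      z1 <- stepping_stone(tree1, trait, "variable",
                           k_stones = config$ss_stones,
                           iters_per_stone = config$ss_iters,
                           seed = sd0 + 1, config = cfg)
      z0 <- stepping_stone(tree1, trait, "homogeneous",
                           k_stones = config$ss_stones,
                           iters_per_stone = config$ss_iters,
                           seed = sd0 + 2, config = cfg)
      bf <- bayes_factor(z1$log_evidence, z0$log_evidence)
      rtt <- rates_through_time(tree1, post$mean_scalars, bins)
      utils::write.csv(post$samples, out_file("trait_rates_trace.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(edge = seq_along(post$mean_scalars),
                   mean_scalar = post$mean_scalars),
        out_file("trait_rates_scalars.csv"), row.names = FALSE)
      utils::write.csv(rtt$mean, out_file("trait_rates_through_time.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(logZ_variable = z1$log_evidence,
                   logZ_homogeneous = z0$log_evidence,
                   logBF = bf$logBF, evidence = bf$evidence),
        out_file("trait_rates_bayes_factor.csv"), row.names = FALSE)
      emit(out_file("trait_rates_trace.csv"), "trait_rates")
      emit(out_file("trait_rates_scalars.csv"), "trait_rates")
      emit(out_file("trait_rates_through_time.csv"), "trait_rates")
      emit(out_file("trait_rates_bayes_factor.csv"), "trait_rates")
      list(posterior = post, bayes_factor = bf, rtt = rtt,
           logZ = c(variable = z1$log_evidence,
                    homogeneous = z0$log_evidence))
    }, error = function(e) e)
    if (inherits(res, "error")) fail("trait_rates", res)
    else { outputs$trait_rates <- res; done <- c(done, "trait_rates") }
  }

  .write_pipeline_reports(config, files, stage_of, failures, out_file)
  list(outputs = outputs,
       manifest = .read_manifest(out_file("manifest.csv")),
       failures = failures)
}

.validate_config <- function(config) {
  if (isTRUE(config$scenario)) return(invisible(config))
  req <- c(distances = "nexus", disparity = "ranges_csv",
           tests = "ranges_csv", timescale = "trees_newick",
           discrete_rates = "nexus", trait_rates = "trait_csv")
  for (stage in intersect(names(req), config$stages)) {
    field <- req[[stage]]
    if (is.null(config[[field]]))
      stop(sprintf("config field `%s` required for stage `%s`",
                   field, stage))
  }
  if ("timescale" %in% config$stages &&
      config$dating_method == "hedman" && is.null(config$outgroups_csv))
    stop("config field `outgroups_csv` required for hedman dating")
  invisible(config)
}

.load_inputs <- function(config) {
  if (isTRUE(config$scenario)) {
    sc <- simulate_scenario(n_taxa = config$n_taxa, n_char = config$n_char,
                            seed = stage_seed(config$seed, "scenario"))
    trees <- replicate(max(config$n_trees, 1),
                       { t <- sc$tree; class(t) <- "phylo"; t },
                       simplify = FALSE)
    return(list(matrix = sc$matrix, ranges = sc$ranges, trees = trees,
                outgroup_ages = sc$outgroup_ages, trait = sc$trait,
                bins = sc$bins, truth = sc$truth))
  }
  matrix <- if (!is.null(config$nexus)) read_nexus_matrix(config$nexus)
  ranges <- if (!is.null(config$ranges_csv)) read_strat_ranges(config$ranges_csv)
  trees <- if (!is.null(config$trees_newick)) {
    tl <- ape::read.tree(config$trees_newick)
    if (inherits(tl, "phylo")) list(tl) else unclass(tl)
  }
  outg <- if (!is.null(config$outgroups_csv)) read_outgroup_ages(config$outgroups_csv)
  trait <- if (!is.null(config$trait_csv)) read_trait_csv(config$trait_csv)
  bins <- if (!is.null(ranges))
    make_bins(config$bin_scheme, oldest = max(ranges$fad),
              youngest = min(ranges$lad), width = config$bin_width)
  else make_bins(config$bin_scheme, width = config$bin_width)
  list(matrix = matrix, ranges = ranges, trees = trees,
       outgroup_ages = outg, trait = trait, bins = bins)
}

.write_pipeline_reports <- function(config, files, stage_of, failures,
                                    out_file) {
  cfg_path <- out_file("config.csv")
  flat <- vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ";"), "")
  utils::write.csv(data.frame(key = names(flat), value = unname(flat)),
                   cfg_path, row.names = FALSE)
  files <- c(files, cfg_path); stage_of <- c(stage_of, "config")
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stage = stage_of, stringsAsFactors = FALSE)
  utils::write.csv(manifest, out_file("manifest.csv"), row.names = FALSE)
  if (nrow(failures))
    utils::write.csv(failures, out_file("failure_report.csv"),
                     row.names = FALSE)
  invisible(manifest)
}

.read_manifest <- function(path) {
  if (file.exists(path)) utils::read.csv(path, stringsAsFactors = FALSE)
  else data.frame(file = character(0), md5 = character(0),
                  stage = character(0))
}

#' Verify a previous pipeline run against its manifest
#'
#' Recomputes the md5 hash of every file listed in `manifest.csv` in an
#' output directory and reports mismatches.
#'
#' @param output_dir pipeline output directory.
#' @return logical: TRUE when every listed file exists and matches;
#'   attribute `mismatches` names the offending files.
#' @export
verify_manifest <- function(output_dir) {
  manifest <- .read_manifest(file.path(output_dir, "manifest.csv"))
  if (!nrow(manifest)) stop("no manifest found in ", output_dir)
  paths <- file.path(output_dir, manifest$file)
  now <- unname(tools::md5sum(paths))
  bad <- manifest$file[is.na(now) | now != manifest$md5]
  out <- length(bad) == 0
  attr(out, "mismatches") <- bad
  out
}
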