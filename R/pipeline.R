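#' End-to-end pipeline configuration
#'
#' Either simulate a cohort (`simulation` config) or load one from disk
#' (`cohort_path` / `metadata_path`), then run distance, lens, Mapper,
#' coloring, enrichment and the confirmatory GLM stages, writing every
#' artifact plus a manifest into `out_dir`. The seed governs only the
#' simulation stage; every analysis stage is deterministic.
#'
#' @param out_dir Output directory.
#' @param simulation A [simulation_config()] (default), or `NULL` when
#'   loading from disk.
#' @param cohort_path,metadata_path Input files when not simulating.
#' @param cover A [cover_config()].
#' @param impute Imputation strategy for [standardize_columns()].
#' @param lens_max_iter,lens_tol Passed to [optimize_lens()].
#' @param selection Node predicate for [select_subgroup()].
#' @param glm_snps SNP columns for [repeated_measures_suite()].
#' @param color_variables Variables to tabulate per node.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            simulation = simulation_config(),
                            cohort_path = NULL, metadata_path = NULL,
                            cover = cover_config(),
                            impute = "median",
                            lens_max_iter = 300, lens_tol = 1e-6,
                            selection = "gose_6m < 5 & ct_pathology == 0",
                            glm_snps = "PARP1",
                            color_variables = c("ct_pathology", "ptsd_dx",
                                                "gose_3m", "gose_6m")) {
  structure(list(out_dir = out_dir, simulation = simulation,
                 cohort_path = cohort_path, metadata_path = metadata_path,
                 cover = cover, impute = impute,
                 lens_max_iter = lens_max_iter, lens_tol = lens_tol,
                 selection = selection, glm_snps = glm_snps,
                 color_variables = color_variables),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; recognized keys mirror [pipeline_config()]
#'   arguments, with `simulation:` and `cover:` as nested maps.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation))
    do.call(simulation_config, y$simulation) else
      if (is.null(y$cohort_path)) simulation_config() else NULL
  cover <- if (!is.null(y$cover)) do.call(cover_config, y$cover) else
    cover_config()
  args <- y[setdiff(names(y), c("simulation", "cover"))]
  do.call(pipeline_config, c(args, list(simulation = sim, cover = cover)))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full syndromic-mapping pipeline
#'
#' Stages: cohort (simulate or load) -> distance -> lens -> map -> color ->
#' enrich -> glm. Each stage writes its artifact (CSV / GraphML / JSON) and
#' the manifest records per-artifact MD5 checksums, so identical
#' configuration and seed reproduce identical bytes. A stage failure aborts
#' with the stage name; artifacts already written are kept.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest (invisibly also written as `manifest.json`), a list
#'   with per-stage status and artifact checksums.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  stages <- list()
  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    stages[[stage]] <<- "ok"
    res
  }
  out <- function(name) file.path(cfg$out_dir, name)

  cohort <- run_stage("cohort", function() {
    if (!is.null(cfg$simulation)) {
      co <- generate_cohort(cfg$simulation)
      write_cohort(co, out("cohort.csv"))
      utils::write.csv(truth_labels(co), out("truth_labels.csv"),
                       row.names = FALSE)
      artifacts <<- c(artifacts, out("cohort.csv"), out("truth_labels.csv"))
      stage_log("cohort", "simulated %d patients (seed %d)",
                n_patients(co), cfg$simulation$seed)
      co
    } else {
      co <- load_cohort(cfg$cohort_path, cfg$metadata_path, require_tda = TRUE)
      stage_log("cohort", "loaded %d patients from %s", n_patients(co),
                cfg$cohort_path)
      co
    }
  })

  d <- run_stage("distance", function() {
    std <- standardize_columns(cohort, impute = cfg$impute)
    dm <- pairwise_distances(std)
    write_distance_matrix(dm, out("distance.csv"))
    artifacts <<- c(artifacts, out("distance.csv"))
    stage_log("distance", "%d x %d norm-correlation matrix",
              n_patients(cohort), n_patients(cohort))
    dm
  })

  lens <- run_stage("lens", function() {
    le <- optimize_lens(d, max_iter = cfg$lens_max_iter, tol = cfg$lens_tol)
    write_lens(le, out("lens.csv"))
    artifacts <<- c(artifacts, out("lens.csv"))
    stage_log("lens", "stress %.4g after %d iterations", le$stress,
              le$iterations)
    le
  })

  graph <- run_stage("map", function() {
    g <- build_graph(lens, d, cohort, cfg$cover)
    write_mapper_graph(g, out("graph.graphml"), out("graph.json"))
    artifacts <<- c(artifacts, out("graph.graphml"), out("graph.json"))
    stage_log("map", "%d nodes, %d edges", nrow(g$node_table), nrow(g$edges))
    g
  })

  run_stage("color", function() {
    cols <- intersect(cfg$color_variables, colnames(graph$stats))
    tabs <- lapply(cols, function(v) {
      ct <- color_graph(graph, v)
      names(ct)[2:3] <- paste0(v, c("_mean", "_n"))
      ct
    })
    tab <- Reduce(function(a, b) merge(a, b, by = "node_id"), tabs)
    utils::write.csv(tab, out("node_colors.csv"), row.names = FALSE)
    artifacts <<- c(artifacts, out("node_colors.csv"))
    stage_log("color", "%d variables over %d nodes", length(cols),
              nrow(graph$node_table))
    tab
  })

  enrich <- run_stage("enrich", function() {
    sel <- select_subgroup(graph, predicate = cfg$selection)
    panel <- enrichment_panel(sel, cohort)
    utils::write.csv(panel, out("enrichment.csv"), row.names = FALSE)
    artifacts <<- c(artifacts, out("enrichment.csv"))
    stage_log("enrich", "%d members vs %d; top categorical: %s",
              length(sel$member_ids), length(sel$complement_ids),
              if (any(panel$family == "categorical"))
                panel$variable[panel$family == "categorical"][1] else "none")
    list(selection = sel, panel = panel)
  })

  reports <- run_stage("glm", function() {
    reps <- lapply(cfg$glm_snps, function(snp) {
      ds <- build_glm_dataset(cohort, snp)
      rep <- repeated_measures_suite(ds)
      artifacts <<- c(artifacts, write_anova_report(rep, out(paste0("glm_", snp))))
      rep
    })
    names(reps) <- cfg$glm_snps
    stage_log("glm", "%d SNP model(s)", length(reps))
    reps
  })

  files <- artifacts[file.exists(artifacts)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("syndromap")),
    seed = if (!is.null(cfg$simulation)) cfg$simulation$seed else NA,
    stages = stages,
    artifacts = lapply(stats::setNames(
      files, sub(paste0("^", cfg$out_dir, "/?"), "", files)), function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, cohort = cohort, distance = d,
                 lens = lens, graph = graph, enrichment = enrich,
                 glm = reports))
}
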