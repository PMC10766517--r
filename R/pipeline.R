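#' Default end-to-end pipeline configuration
#'
#' Nested list of every stage parameter, validated against this template
#' by [validate_pipeline_config()] (unknown keys are rejected). Stage
#' seeds derive from the master `seed` via [stage_seed()], so each stage is
#' independently reproducible.
#'
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    n_total = 400L,
    fixture = list(n_somas = NULL, oversample = 1.2),
    geometry = list(length_um = 6000, width_um = 3000, thickness_um = 1500,
                    gyrification_amplitude = 200,
                    gyrification_wavelength = 2000, bend_depth = 600,
                    so_frac = 0.2, sr_frac = 0.55, slm_frac = 0.85,
                    grid_spacing = 25),
    imaging = list(xy_resolution = 20, z_resolution = 20,
                   soma_intensity = 30, background_intensity = 200,
                   noise_sd = 0),
    profile = list(stratum_weights = c(so = 0.1, sp = 0.7, sr = 0.15,
                                       slm = 0.05),
                   sp_gradient = 3, longitudinal_ramp = 2),
    classes = list(inhibitory_ratio = 0.10,
                   proportions = c(Perisomatic = 0.22, OLM = 0.07,
                                   IVY = 0.15, TRI = 0.04, SCA = 0.13,
                                   PPA = 0.12, NGF = 0.27),
                   shift_gains = c(SCA = 0.5, PPA = 0.5, NGF = 1.0),
                   outer_quantile = 0.7),
    morphology = list(scale_factor = 1.5, point_volume = 64000,
                      truncation_floor = 0.2, axon_sample_points = 120,
                      size_scale = 1),
    connectivity = list(p_default = 0.01, interpretation = "product"),
    validation = list(degree_bin_width = 10, length_bin_width = 100,
                      hub_k_sd = 3, baseline = TRUE),
    stages = list(render = TRUE, density = TRUE, connectivity = TRUE,
                  validation = TRUE),
    output = list(stack_format = "tiff")),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks the nested structure against [default_pipeline_config()]:
#' unknown keys anywhere are rejected, missing keys are filled from the
#' defaults, and basic value constraints are enforced before any stage
#' runs.
#'
#' @param config a (possibly partial) configuration list.
#' @return the completed, validated `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  template <- default_pipeline_config()
  merge_checked <- function(tmpl, cfg, path = "") {
    unknown <- setdiff(names(cfg), names(tmpl))
    if (length(unknown))
      stop("unknown configuration key", if (length(unknown) > 1) "s",
           ": ", paste0(path, unknown, collapse = ", "))
    for (k in names(cfg)) {
      if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]]))) {
        tmpl[[k]] <- merge_checked(tmpl[[k]], as.list(cfg[[k]]),
                                   paste0(path, k, "/"))
      } else if (!is.null(cfg[[k]])) {
        v <- cfg[[k]]
        if (is.list(v)) v <- unlist(v)
        if (!is.null(names(tmpl[[k]])) && is.null(names(v)) &&
            length(v) == length(tmpl[[k]]))
          names(v) <- names(tmpl[[k]])
        tmpl[[k]] <- v
      }
    }
    tmpl
  }
  out <- merge_checked(unclass(template), as.list(config))
  if (out$n_total < 1) stop("n_total must be >= 1")
  if (out$fixture$oversample <= 1)
    stop("fixture oversample must exceed 1")
  # constructor calls validate their own blocks
  do.call(class_config, out$classes)
  do.call(make_imaging_params, out$imaging)
  structure(out, class = "pipeline_config")
}

#' Run the full scaffold pipeline
#'
#' Executes fixture generation, rendering, segmentation, pruning and class
#' assignment, density analysis, morphology generation, touch-detection
#' connectivity with pruning, and topology validation, writing every
#' declared artifact plus a run manifest into `outdir`. Identical
#' config + seed reproduce identical outputs byte for byte.
#'
#' @param config a [default_pipeline_config()]-shaped list.
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory stage products and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir) {
  config <- validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  files <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  geometry <- run_stage("geometry",
    do.call(make_mini_ca1_landmarks, config$geometry))
  landmarks <- geometry_landmarks(geometry)
  cls_cfg <- do.call(class_config, config$classes)
  imaging <- do.call(make_imaging_params, config$imaging)
  profile <- do.call(density_profile, config$profile)

  n_fix <- config$fixture$n_somas
  if (is.null(n_fix))
    n_fix <- ceiling(config$n_total * config$fixture$oversample)
  truth_placement <- run_stage("placement",
    make_toy_placement(geometry, n_fix, profile,
                       seed = stage_seed(seed, "placement"),
                       config = NULL))

  if (isTRUE(config$stages$render)) {
    rendered <- run_stage("render",
      render_synthetic_stack(truth_placement, imaging,
                             seed = stage_seed(seed, "render")))
    stack_path <- file.path(outdir,
      if (config$output$stack_format == "tiff") "stack.tiff" else "stack_png")
    write_stack(rendered$stack, stack_path, config$output$stack_format)
    truth_path <- file.path(outdir, "ground_truth.csv")
    write.csv(rendered$truth, truth_path, row.names = FALSE)
    files <- c(files, stack_path, truth_path)
    somas <- run_stage("segment", segment_stack(rendered$stack, imaging))
  } else {
    somas <- truth_placement[, c("gid", "x", "y", "z")]
  }

  placement <- run_stage("prune",
    prune_to_population(somas, config$n_total, cls_cfg,
                        seed = stage_seed(seed, "prune")))
  placement <- run_stage("classes",
    assign_interneuron_classes(placement, landmarks, cls_cfg,
                               seed = stage_seed(seed, "classes")))
  placement_path <- file.path(outdir, "placement.txt")
  write_placement_text(placement, placement_path)
  files <- c(files, placement_path)

  density <- NULL
  if (isTRUE(config$stages$density)) {
    density <- run_stage("density", {
      grid <- voxel_density(placement)
      trans <- transversal_profile(placement, geometry)
      longi <- longitudinal_profile(placement, geometry,
                                    seed = stage_seed(seed, "density"))
      grid_path <- file.path(outdir, "density_grid.csv")
      write_density_csv(grid, grid_path)
      files <<- c(files, grid_path)
      list(grid = grid, transversal = trans, longitudinal = longi)
    })
  }

  connections <- NULL
  morphologies <- NULL
  if (isTRUE(config$stages$connectivity)) {
    mp <- default_morphology_params(
      scale_factor = config$morphology$scale_factor,
      point_volume = config$morphology$point_volume,
      truncation_floor = config$morphology$truncation_floor,
      axon_sample_points = config$morphology$axon_sample_points)
    morphologies <- run_stage("morphology",
      build_morphologies(placement, landmarks, mp,
                         seed = stage_seed(seed, "morphology"),
                         size_scale = config$morphology$size_scale))
    candidates <- run_stage("connect", find_candidate_pairs(morphologies))
    sizes <- table(factor(placement$class, levels = scaffold_classes()))
    connections <- run_stage("connect",
      prune_pairs(candidates, default_p_conn(config$connectivity$p_default),
                  setNames(as.integer(sizes), names(sizes)),
                  seed = stage_seed(seed, "connect"),
                  interpretation = config$connectivity$interpretation))
    h5_path <- file.path(outdir, "connectome.h5")
    write_connectome_hdf5(connections, h5_path)
    files <- c(files, h5_path)
  }

  report <- NULL
  if (isTRUE(config$stages$validation) && !is.null(connections) &&
      nrow(connections)) {
    report <- run_stage("validate", {
      bw <- config$validation$degree_bin_width
      dd <- degree_distributions(connections, placement, bw)
      ll <- connection_lengths(connections, placement,
                               config$validation$length_bin_width)
      deg <- degree_counts(connections, placement)
      hubs <- detect_hubs(deg$total, config$validation$hub_k_sd)
      rep <- list(n_neurons = nrow(placement),
                  n_connections = nrow(connections),
                  mean_outdegree = mean(deg$outdegree),
                  hubs = hubs)
      if (isTRUE(config$validation$baseline)) {
        base <- random_baseline(placement, nrow(connections),
                                seed = stage_seed(seed, "baseline"))
        bd <- degree_distributions(base, placement, bw)
        rep$kl_outdegree_vs_random <- kl_compare(dd$outdegree, bd$outdegree)
        rep$kl_indegree_vs_random <- kl_compare(dd$indegree, bd$indegree)
        rep$baseline_hubs <- detect_hubs(
          degree_counts(base, placement)$total, config$validation$hub_k_sd)
      }
      for (nm in c("indegree", "outdegree")) {
        p <- file.path(outdir, paste0(nm, "_histogram.csv"))
        write_histogram_csv(dd[[nm]], p)
        files <<- c(files, p)
      }
      p <- file.path(outdir, "length_histogram.csv")
      write_histogram_csv(ll, p)
      files <<- c(files, p)
      if (!is.null(density)) {
        rep$transversal_percent_increase <- density$transversal$mean
        rep$longitudinal_percent_difference <-
          density$longitudinal$percent_difference
      }
      rp <- file.path(outdir, "validation.json")
      jsonlite::write_json(rep, rp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      files <<- c(files, rp)
      rep
    })
  }

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("ca1scaffold")),
    files = basename(c(files, cfg_path)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(geometry = geometry, placement = placement,
                 density = density, morphologies = morphologies,
                 connections = connections, report = report,
                 manifest = manifest, outdir = outdir))
}
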