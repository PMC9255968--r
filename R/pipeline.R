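.known_config_keys <- c("seed", "output_dir", "log_level", "stages",
                        "simulate", "detect", "morphometry", "dynamics",
                        "profiles", "islets", "smlm3d", "input")

#' Validate a pipeline run configuration
#'
#' @param config named list, or path to a YAML file. Unknown top-level keys
#'   are rejected. Required: \code{output_dir}; \code{seed} defaults to 1.
#' @return the validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    stop("validate_config: unknown key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$output_dir)) stop("validate_config: output_dir is required")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages)) config$stages <- c("simulate", "detect", "morphometry")
  bad <- setdiff(config$stages,
                 c("simulate", "detect", "morphometry", "dynamics", "islets", "smlm3d"))
  if (length(bad)) stop("validate_config: unknown stage(s): ", paste(bad, collapse = ", "))
  config
}

#' Run the analysis pipeline from one configuration
#'
#' Executes the requested stages in dependency order
#' (simulate -> detect -> morphometry / dynamics / islets / smlm3d), writes
#' every stage output under \code{output_dir}, and records parameters, seed,
#' package version and output checksums in \code{manifest.json}. On stage
#' failure, outputs of completed stages are left intact and the manifest
#' records the failure point before the error is re-raised.
#'
#' @param config named list or YAML path; see \code{\link{validate_config}}.
#'   Stage parameter sub-lists are passed to the stage functions; simulation
#'   parameters go under \code{simulate} (fields of
#'   \code{\link{layout_params}} plus optional \code{movie = TRUE} and
#'   \code{localizations = TRUE}).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "podonano",
                   version = as.character(utils::packageVersion("podonano")),
                   seed = cfg$seed, config = cfg, stages = list(), status = "running")
  files <- character(0)
  save_manifest <- function() {
    manifest$outputs <<- lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  add_file <- function(f) files <<- c(files, f)
  ctx <- new.env()
  run_stage <- function(name, fun) {
    if (!(name %in% cfg$stages)) return(invisible())
    ok <- tryCatch({ fun(); TRUE }, error = function(e) e)
    if (isTRUE(ok)) {
      manifest$stages[[name]] <<- list(status = "ok")
    } else {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(ok))
      manifest$status <<- paste0("failed at stage '", name, "'")
      save_manifest()
      stop("run_pipeline: stage '", name, "' failed: ", conditionMessage(ok))
    }
  }
  run_stage("simulate", function() {
    sp <- cfg$simulate
    lp_args <- sp[intersect(names(sp), names(formals(layout_params)))]
    lp_args$seed <- cfg$seed
    params <- do.call(layout_params, lp_args)
    ctx$layout <- make_layout(params)
    write_layout(ctx$layout, file.path(cfg$output_dir, "ground_truth"))
    add_file(file.path(cfg$output_dir, "ground_truth", "cores.csv"))
    add_file(file.path(cfg$output_dir, "ground_truth", "manifest.json"))
    ctx$frame <- render_frame(ctx$layout)
    write_image_tiff(ctx$frame, file.path(cfg$output_dir, "frame.tif"))
    add_file(file.path(cfg$output_dir, "frame.tif"))
    if (isTRUE(sp$movie)) {
      mv <- simulate_movie(ctx$layout, seed = cfg$seed)
      ctx$movie <- mv
      write_stack_tiff(mv$stack, file.path(cfg$output_dir, "movie.tif"))
      add_file(file.path(cfg$output_dir, "movie.tif"))
      utils::write.csv(mv$truth$signals,
                       file.path(cfg$output_dir, "truth_signals.csv"),
                       row.names = FALSE)
      add_file(file.path(cfg$output_dir, "truth_signals.csv"))
    }
    if (isTRUE(sp$localizations)) {
      pr <- protein_spec("paxillin", "ring_at_offset_nm", axial_mean_nm = 139)
      ctx$locs <- simulate_localizations(ctx$layout, pr, 5000, seed = cfg$seed)
      utils::write.csv(ctx$locs, file.path(cfg$output_dir, "localizations.csv"),
                       row.names = FALSE)
      add_file(file.path(cfg$output_dir, "localizations.csv"))
    }
  })
  run_stage("detect", function() {
    if (is.null(ctx$frame)) {
      inp <- cfg$input$image
      if (is.null(inp)) stop("detect stage needs a simulated frame or input$image")
      ctx$frame <- read_image_tiff(inp, cfg$input$pixel_size_nm)
    }
    args <- cfg$detect
    ctx$cores <- do.call(analyze_frame, c(list(ctx$frame), args))
    write_cores(ctx$cores, file.path(cfg$output_dir, "cores_detected.csv"))
    add_file(file.path(cfg$output_dir, "cores_detected.csv"))
  })
  run_stage("morphometry", function() {
    if (is.null(ctx$cores)) {
      inp <- cfg$input$cores
      if (is.null(inp)) stop("morphometry stage needs detected cores or input$cores")
      ctx$cores <- read_cores(inp)
    }
    g <- build_graph(ctx$cores)
    write_graph(g, file.path(cfg$output_dir, "morphometry"))
    add_file(file.path(cfg$output_dir, "morphometry", "edges.csv"))
    dn <- direct_neighbor_stats(g); nn <- nearest_neighbor_stats(g)
    summ <- data.frame(statistic = c("direct_neighbor_pooled_median_nm",
                                     "direct_neighbor_per_vertex_median_nm",
                                     "nearest_neighbor_median_nm"),
                       value = c(dn$pooled_median_nm, dn$per_vertex_median_nm,
                                 nn$median_nm))
    utils::write.csv(summ, file.path(cfg$output_dir, "morphometry", "summary.csv"),
                     row.names = FALSE)
    add_file(file.path(cfg$output_dir, "morphometry", "summary.csv"))
  })
  run_stage("dynamics", function() {
    if (is.null(ctx$movie)) stop("dynamics stage requires simulate with movie: true")
    st <- bleach_correct(ctx$movie$stack)
    cs <- core_set(data.frame(id = ctx$layout$cores$core_id,
                              x_nm = ctx$layout$cores$x_nm,
                              y_nm = ctx$layout$cores$y_nm))
    sig <- extract_signals(st, cs)
    utils::write.csv(cbind(id = sig$ids, as.data.frame(sig$signals)),
                     file.path(cfg$output_dir, "signals.csv"), row.names = FALSE)
    add_file(file.path(cfg$output_dir, "signals.csv"))
    syn <- pairwise_synchrony(sig)
    utils::write.csv(as.data.frame(syn), file.path(cfg$output_dir, "synchrony.csv"),
                     row.names = FALSE)
    add_file(file.path(cfg$output_dir, "synchrony.csv"))
  })
  run_stage("islets", function() {
    if (is.null(ctx$layout)) stop("islets stage requires the simulate stage")
    adh <- render_frame(ctx$layout, protein_spec("vinculin", "islet_border",
                                                 lateral_sd_nm = 80),
                        noise = NULL, background = 0)
    cs <- core_set(data.frame(id = ctx$layout$cores$core_id,
                              x_nm = ctx$layout$cores$x_nm,
                              y_nm = ctx$layout$cores$y_nm))
    seg <- segment_islets(adh, cs)
    utils::write.csv(seg$islets, file.path(cfg$output_dir, "islets.csv"),
                     row.names = FALSE)
    add_file(file.path(cfg$output_dir, "islets.csv"))
  })
  run_stage("smlm3d", function() {
    if (is.null(ctx$locs)) {
      inp <- cfg$input$localizations
      if (is.null(inp)) stop("smlm3d stage needs simulated or input localizations")
      ctx$locs <- read_locs(inp)
    }
    cs <- if (!is.null(ctx$layout))
      core_set(data.frame(id = ctx$layout$cores$core_id,
                          x_nm = ctx$layout$cores$x_nm,
                          y_nm = ctx$layout$cores$y_nm)) else ctx$cores
    geom <- if (!is.null(cfg$smlm3d$geometry)) read_belt_geometry(cfg$smlm3d$geometry)
            else belt_geometry()
    pts <- assign_locs(ctx$locs, cs, geom)
    utils::write.csv(as.data.frame(pts), file.path(cfg$output_dir, "rz_points.csv"),
                     row.names = FALSE)
    add_file(file.path(cfg$output_dir, "rz_points.csv"))
    prof <- bin_rz(pts)
    utils::write.csv(as.data.frame(prof), file.path(cfg$output_dir, "rz_profile.csv"),
                     row.names = FALSE)
    add_file(file.path(cfg$output_dir, "rz_profile.csv"))
  })
  manifest$status <- "ok"
  save_manifest()
  invisible(manifest)
}
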