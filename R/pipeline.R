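#' Pipeline configuration
#'
#' Bundles the tunable parameters of the reconstruction pipeline with their
#' defaults: `rho = 0.15` (triangle edge length as a fraction of the local
#' radius of curvature) and `knn_k = 10` (neighbourhood size for covariance
#' normals) are the method's standard settings; `depth` is the octree depth
#' of the Poisson solve.
#'
#' @param rho edge-scale constant, in (0, 1).
#' @param knn_k neighbour count for normal estimation (>= 3).
#' @param depth octree depth (4..10).
#' @param r_min,r_max curvature-radius clamps (world length); defaults
#'   `0.5 * min(spacing)` and `100 * max(spacing)` are filled in at run
#'   time.
#' @param max_triangles expansion cap.
#' @param seed random seed for the sampled distance metrics.
#' @param samples_per_triangle sampling density of the distance metrics.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rho = 0.15, knn_k = 10, depth = 7, r_min = NULL,
                            r_max = NULL, max_triangles = 200000,
                            seed = 1, samples_per_triangle = 10) {
  if (!(rho > 0 && rho < 1)) stop("rho must be in (0, 1)")
  if (knn_k < 3) stop("knn_k must be at least 3")
  if (depth < 4 || depth > 10) stop("depth must be between 4 and 10")
  structure(list(rho = rho, knn_k = knn_k, depth = depth, r_min = r_min,
                 r_max = r_max, max_triangles = max_triangles, seed = seed,
                 samples_per_triangle = samples_per_triangle),
            class = "pipeline_config")
}

#' Reconstruct a surface from a binary volume
#'
#' Runs the full pipeline: boundary point extraction, covariance normal
#' estimation and orientation, Poisson indicator function, seed + expansion,
#' gap stitching with patch subdivision. Deterministic for a fixed config
#' and input.
#'
#' @param vol a [binary_volume()] (or an `analytic_shape`, which is then
#'   rasterized at unit spacing).
#' @param config a [pipeline_config()].
#' @param verbose print per-stage timings and counts.
#' @return list: `mesh` (closed [triangle_mesh()]), `field`, `cloud`, and
#'   `log` (per-stage counts and timings).
#' @export
reconstruct_surface <- function(vol, config = pipeline_config(),
                                verbose = FALSE) {
  if (inherits(vol, "analytic_shape")) vol <- rasterize(vol)
  stopifnot(inherits(vol, "binary_volume"))
  log <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    res <- force(expr)
    log[[stage]] <<- list(seconds = unname(proc.time()[3] - t0))
    if (verbose) message(sprintf("[%s] %.2fs", stage, log[[stage]]$seconds))
    res
  }
  samples <- tick("extract", extract_points(vol))
  log$extract$n_samples <- nrow(samples)
  cloud <- tick("normals", orient_normals(samples, vol, k = config$knn_k))
  field <- tick("poisson", poisson_field(cloud, depth = config$depth))
  log$poisson$n_nodes <- field$n^3
  r_min <- if (is.null(config$r_min)) 0.5 * min(vol$spacing) else config$r_min
  r_max <- if (is.null(config$r_max)) 100 * max(vol$spacing) else config$r_max
  grown <- tick("expand", {
    ctr <- colMeans(cloud$positions)
    d2 <- rowSums(sweep(cloud$positions, 2, ctr)^2)
    # try several seed candidates: a sample in a concave notch or on a flat
    # plateau may not admit a regular tangent hexagon
    cand_order <- order(d2)
    cand_order <- cand_order[unique(pmin(length(cand_order),
                                         floor(seq(1, length(cand_order),
                                                   length.out = 20))))]
    M <- NULL
    for (ci in cand_order) {
      M <- tryCatch(seed_mesh(field, cloud$positions[ci, ],
                              rho = config$rho, r_min = r_min, r_max = r_max),
                    error = function(e) NULL)
      if (!is.null(M)) break
    }
    if (is.null(M)) stop("no sample point admitted a seed hexagon")
    expand_all(M, field, rho = config$rho,
               max_triangles = config$max_triangles)
    # re-seed any uncovered component
    for (comp in seq_len(10)) {
      mesh_now <- finalize_mesh(M)
      dist_s <- cpp_point_mesh_dist(cloud$positions, mesh_now$vertices,
                                    mesh_now$faces)
      far <- which(dist_s > 2 * r_max)
      if (length(far) == 0) break
      M <- seed_mesh(field, cloud$positions[far[which.max(dist_s[far])], ],
                     rho = config$rho, r_min = r_min, r_max = r_max, mesh = M)
      expand_all(M, field, rho = config$rho,
                 max_triangles = config$max_triangles)
    }
    M
  })
  log$expand$n_triangles <- grown$nf
  log$expand$stats <- grown$stats
  open_mesh <- finalize_mesh(grown)
  log$expand$n_boundary_edges <- nrow(boundary_edges(grown))
  mesh <- tick("stitch", stitch_gaps(open_mesh, field, subdivide = TRUE,
                                     target_euler = volume_surface_euler(vol)))
  log$stitch$n_patch_faces <- length(attr(mesh, "patch_faces"))
  log$stitch$n_faces_total <- nrow(mesh$faces)
  list(mesh = mesh, field = field, cloud = cloud, volume = vol, log = log)
}

#' Quality report for a reconstructed mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param reference optional reference surface ([triangle_mesh()] or
#'   `analytic_shape`) for the distance statistics.
#' @param config a [pipeline_config()]; `seed` fixes the distance sampling.
#' @param curvature whether to compute the per-vertex RMS curvature map.
#' @return A `quality_report` list: edge-ratio histogram and tail
#'   fractions, distance stats (when a reference is given), topology, and
#'   optionally per-vertex curvature.
#' @export
quality_report <- function(mesh, reference = NULL,
                           config = pipeline_config(), curvature = FALSE) {
  er <- edge_ratio_report(mesh)
  rep <- list(
    n_vertices = nrow(mesh$vertices),
    n_triangles = nrow(mesh$faces),
    edge_ratio_histogram = as.list(er$histogram),
    fraction_tau_below_0.3 = er$fraction_below(0.3),
    fraction_tau_atleast_0.8 = er$fraction_atleast(0.8),
    topology = topology_report(mesh))
  if (!is.null(reference)) {
    set.seed(config$seed)
    rep$distance <- surface_distance(
      mesh, reference, samples_per_triangle = config$samples_per_triangle)
  }
  if (curvature) rep$curvature_per_vertex <- as.numeric(rms_curvature(mesh))
  class(rep) <- "quality_report"
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report: %d triangles, %.1f%% tau>=0.8, %.2f%% tau<0.3\n",
              x$n_triangles, 100 * x$fraction_tau_atleast_0.8,
              100 * x$fraction_tau_below_0.3))
  cat(sprintf("  topology: euler %d, %d component(s), %d boundary edges, manifold %s\n",
              x$topology$euler, x$topology$components,
              x$topology$boundary_edges, x$topology$manifold))
  if (!is.null(x$distance))
    cat(sprintf("  distance: mean %.4f, max %.4f, rms %.4f\n",
                x$distance$mean, x$distance$max, x$distance$rms))
  invisible(x)
}

#' Run the full pipeline with file I/O
#'
#' @param input path to a segmentation volume, a [binary_volume()], or an
#'   `analytic_shape` phantom.
#' @param mesh_out optional output mesh path (PLY/OBJ/STL).
#' @param report_out optional output JSON report path.
#' @param config a [pipeline_config()].
#' @param reference optional reference for the distance metrics.
#' @param verbose print stage progress.
#' @return list with `mesh`, `report` and the stage `log`, invisibly when
#'   writing files.
#' @export
run_pipeline <- function(input, mesh_out = NULL, report_out = NULL,
                         config = pipeline_config(), reference = NULL,
                         verbose = FALSE) {
  vol <- if (is.character(input)) load_volume(input) else input
  res <- reconstruct_surface(vol, config, verbose = verbose)
  rep <- quality_report(res$mesh, reference = reference, config = config)
  rep$config <- unclass(config)
  rep$log <- res$log
  if (!is.null(mesh_out)) save_mesh(res$mesh, mesh_out)
  if (!is.null(report_out))
    jsonlite::write_json(.report_json(rep), report_out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  out <- list(mesh = res$mesh, report = rep, log = res$log, field = res$field)
  if (is.null(mesh_out) && is.null(report_out)) out else invisible(out)
}

.report_json <- function(rep) {
  r <- unclass(rep)
  r$topology <- lapply(r$topology, function(v) if (is.logical(v)) unclass(v) else v)
  r$log <- lapply(r$log, function(st) lapply(st, function(v)
    if (is.numeric(v) || is.integer(v)) as.numeric(v) else v))
  r
}
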