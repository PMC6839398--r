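#' Run the full analysis pipeline on synthetic populations
#'
#' Orchestrates generate -> profile -> compare -> cluster -> composition ->
#' consensus over one or more synthetic populations, writing plain-file
#' intermediates (CSV, SVG) and a JSON manifest recording package version,
#' configuration, derived per-stage seeds and output digests, so a run is
#' reproducible and diffable. All stage seeds are derived deterministically
#' from the single pipeline seed.
#'
#' @param config named list with at least `out_dir`, `seed` and
#'   `populations` (a list of argument lists for [population_spec()]).
#'   Optional: `window_fraction` (0.05), `n_index` (100), `k` (clusters;
#'   `NULL` selects by silhouette), `cluster_on` ("profile" or
#'   "embedding"), `perplexity`, `max_iter` (t-SNE settings when embedding),
#'   `scale_mode` for consensus building.
#' @return the manifest, invisibly; all outputs under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  for (field in c("out_dir", "seed", "populations"))
    if (is.null(config[[field]]))
      stop("config is missing required field: ", field)
  defaults <- list(window_fraction = 0.05, n_index = 100, k = NULL,
                   cluster_on = "profile", perplexity = 100, max_iter = 1000,
                   scale_mode = "size-preserving")
  cfg <- modifyList(defaults, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- vapply(c("generate", "embed"), function(s)
    derive_seed(cfg$seed, s), integer(1))

  # generate
  pops <- lapply(seq_along(cfg$populations), function(i) {
    args <- cfg$populations[[i]]
    if (is.null(args$seed)) args$seed <- derive_seed(stage_seed["generate"], i)
    generate_population(do.call(population_spec, args))
  })
  cells <- do.call(rbind, lapply(pops, `[[`, "cells"))
  outlines <- do.call(c, lapply(pops, `[[`, "outlines"))
  write.csv(cells, file.path(cfg$out_dir, "cells.csv"), row.names = FALSE)

  # profiles anchored at the hook apex
  profiles <- lapply(outlines, function(o)
    detect_hook_apex(angle_profile(o, window_fraction = cfg$window_fraction,
                                   n_index = cfg$n_index)))
  write_profiles_csv(profiles, cells[, c("id", "genotype", "sex")],
                     file.path(cfg$out_dir, "profiles.csv"))

  # morphometrics + X/Y comparison
  morpho <- do.call(rbind, lapply(pops, population_morphometry,
                                  window_fraction = cfg$window_fraction,
                                  n_index = cfg$n_index))
  write.csv(morpho, file.path(cfg$out_dir, "morphometry.csv"), row.names = FALSE)
  xy <- tryCatch(compare_xy(morpho), error = function(e) NULL)
  if (!is.null(xy))
    write.csv(xy, file.path(cfg$out_dir, "xy_tests.csv"), row.names = FALSE)

  # clustering (profile space by default; embedding mode records its seed)
  feats <- profiles_to_matrix(profiles)
  embedding <- NULL
  if (cfg$cluster_on == "embedding") {
    embedding <- embed_profiles(feats, perplexity = cfg$perplexity,
                                max_iter = cfg$max_iter,
                                seed = stage_seed["embed"])
    write.csv(data.frame(id = cells$id, x = embedding[, 1], y = embedding[, 2]),
              file.path(cfg$out_dir, "embedding.csv"), row.names = FALSE)
    feats <- embedding
  }
  assignment <- cluster_profiles(feats, k = cfg$k, ids = cells$id)
  write.csv(data.frame(id = cells$id, cluster = assignment$labels),
            file.path(cfg$out_dir, "clusters.csv"), row.names = FALSE)
  composition <- cluster_sex_composition(assignment, cells$sex)
  write.csv(composition, file.path(cfg$out_dir, "cluster_composition.csv"),
            row.names = FALSE)

  # consensus shapes per genotype and per cluster
  cons_gt <- group_consensus(outlines, cells$genotype, scale_mode = cfg$scale_mode)
  cons_cl <- group_consensus(outlines, assignment$labels, scale_mode = cfg$scale_mode)
  write_outline_svg(cons_gt, file.path(cfg$out_dir, "consensus_genotype.svg"))
  write_outline_svg(cons_cl, file.path(cfg$out_dir, "consensus_cluster.svg"))
  for (nm in names(cons_gt))
    write.csv(as_vertices(cons_gt[[nm]]$mean_outline),
              file.path(cfg$out_dir, sprintf("consensus_%s.csv", nm)),
              row.names = FALSE)

  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "spermshape",
    version = as.character(utils::packageVersion("spermshape")),
    seed = cfg$seed,
    stage_seeds = as.list(stage_seed),
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_cells = nrow(cells),
    k = assignment$k,
    feature_space = assignment$feature_space,
    digests = as.list(tools::md5sum(files))
  )
  names(manifest$digests) <- basename(files)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
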