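# Pipeline orchestration: one declarative config (YAML or list), stages in
# dependency order (data -> thin -> K diagnostics -> sibp -> stats/kde),
# versioned outputs plus a manifest of parameters, seeds and checksums.

default_config <- function() {
  list(
    seed = 1,
    input = NULL,  # list(genepop=..., coords=..., coord_mode=...) or NULL
    simulate = list(mode = "hierarchical"),
    thinning = list(enabled = TRUE, cut_km = 50, max_per_cluster = 10,
                    linkage = "complete"),
    kdiag = list(enabled = FALSE, K_values = 1:4, replicates = 4),
    sibp = list(threshold = 0.70, replicates = 10, min_group = 10,
                max_depth = 8),
    stats = list(enabled = TRUE, hwp_reps = 0, correlog = TRUE,
                 n_classes = 20, reps = 199),
    kde = list(enabled = TRUE, levels = c(0.25, 0.50, 0.75), min_group = 5)
  )
}

validate_config <- function(cfg) {
  known <- names(default_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop("unknown config block(s): ", paste(extra, collapse = ", "))
  }
  base <- default_config()
  for (nm in known) {
    if (is.list(base[[nm]]) && !is.null(cfg[[nm]])) {
      bad <- setdiff(names(cfg[[nm]]), c(names(base[[nm]]), "mode", "args"))
      if (length(bad) > 0 && nm != "simulate" && nm != "input") {
        stop("unknown field(s) in config block '", nm, "': ",
             paste(bad, collapse = ", "))
      }
      base[[nm]] <- utils::modifyList(base[[nm]], cfg[[nm]])
    } else if (!is.null(cfg[[nm]])) {
      base[[nm]] <- cfg[[nm]]
    }
  }
  th <- base$sibp$threshold
  if (!is.numeric(th) || th <= 0.5 || th >= 1) {
    stop("config field sibp.threshold must lie in (0.5, 1), got ", th)
  }
  if (base$thinning$cut_km <= 0) {
    stop("config field thinning.cut_km must be > 0")
  }
  if (base$sibp$min_group < 2) {
    stop("config field sibp.min_group must be >= 2")
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: data acquisition (files named in
#' `input`, or a seeded simulation), spatial thinning, optional K
#' diagnostics, the spatial iterative bifurcation process, per-center
#' diversity/divergence statistics with an optional Mantel correlogram,
#' and KDE center polygons.  Every artifact is written under `out_dir`
#' together with a `manifest.json` recording parameters, derived seeds,
#' and md5 checksums of all outputs.  Config validation happens before any
#' computation; invalid fields are reported by name.
#'
#' @param config a config list, or path to a YAML file with the same
#'   structure (unknown fields are rejected).  See the vignette for the
#'   block layout.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  durations <- list()
  stage <- function(name, code) {
    s <- Sys.time()
    r <- tryCatch(force(code), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    durations[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    r
  }

  sp <- stage("data", {
    if (!is.null(cfg$input)) {
      gt <- read_genepop(cfg$input$genepop)
      geo <- read_coords_csv(cfg$input$coords,
                             mode = cfg$input$coord_mode %||% "planar_km")
      attach_coords(gt, geo)
    } else {
      args <- cfg$simulate[setdiff(names(cfg$simulate), "mode")]
      args$seed <- args$seed %||% derive_seed(cfg$seed, "simulate")
      sim <- if ((cfg$simulate$mode %||% "hierarchical") == "stepping_stone") {
        do.call(simulate_stepping_stone, args)
      } else {
        do.call(simulate_hierarchical, args)
      }
      utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
      sim$data
    }
  })

  if (isTRUE(cfg$thinning$enabled)) {
    thr <- stage("thinning", {
      thin(sp, cut_km = cfg$thinning$cut_km,
           max_per_cluster = cfg$thinning$max_per_cluster,
           linkage = cfg$thinning$linkage,
           seed = derive_seed(cfg$seed, "thin"))
    })
    utils::write.csv(thr$report, file.path(out_dir, "thinning_report.csv"),
                     row.names = FALSE)
    sp <- thr$data
  }

  if (isTRUE(cfg$kdiag$enabled)) {
    kd <- stage("kdiag", {
      admixture_scan(sp$geno, cfg$kdiag$K_values,
                     replicates = cfg$kdiag$replicates,
                     seed = derive_seed(cfg$seed, "kdiag"))
    })
    utils::write.csv(kd$diagnostics, file.path(out_dir, "k_diagnostics.csv"),
                     row.names = FALSE)
  }

  sres <- stage("sibp", {
    run_sibp(sp, threshold = cfg$sibp$threshold,
             replicates = cfg$sibp$replicates,
             min_group = cfg$sibp$min_group, max_depth = cfg$sibp$max_depth,
             seed = derive_seed(cfg$seed, "sibp"))
  })
  sibp_tree_json(sres, file.path(out_dir, "tree.json"))
  sibp_tree_newick(sres, file.path(out_dir, "tree.nwk"))
  utils::write.csv(sres$centers, file.path(out_dir, "centers.csv"),
                   row.names = FALSE)
  utils::write.csv(sibp_attrition(sres), file.path(out_dir, "attrition.csv"),
                   row.names = FALSE)

  centers_gl <- split(sres$centers$id, sres$centers$center)
  if (isTRUE(cfg$stats$enabled)) {
    stage("stats", {
      div_groups <- c(list(all = sp$geno$ids), centers_gl)
      ds <- diversity_summary(sp$geno, div_groups)
      utils::write.csv(ds, file.path(out_dir, "diversity.csv"),
                       row.names = FALSE)
      big <- names(centers_gl)[lengths(centers_gl) >= 2]
      if (length(big) >= 2) {
        for (statn in c("theta_st", "jost_d")) {
          m <- divergence_matrix(sp$geno, centers_gl[big], statistic = statn)
          utils::write.csv(as.data.frame(m),
                           file.path(out_dir, paste0(statn, ".csv")))
        }
      }
      if (isTRUE(cfg$stats$correlog) && n_ind(sp$geno) >= 10) {
        cg <- mantel_correlog(stats::dist(sp$coords), amova_distance(sp$geno),
                              n_classes = cfg$stats$n_classes,
                              reps = cfg$stats$reps,
                              seed = derive_seed(cfg$seed, "correlog"))
        utils::write.csv(as.data.frame(cg),
                         file.path(out_dir, "correlogram.csv"),
                         row.names = FALSE)
      }
      if (cfg$stats$hwp_reps > 0) {
        hw <- hwp_tests(sp$geno, centers_gl, reps = cfg$stats$hwp_reps,
                        seed = derive_seed(cfg$seed, "hwp"))
        utils::write.csv(hw, file.path(out_dir, "hwp_tests.csv"),
                         row.names = FALSE)
      }
      NULL
    })
  }

  if (isTRUE(cfg$kde$enabled)) {
    stage("kde", {
      ok <- sres$centers$id[sres$centers$center %in%
                              names(centers_gl)[lengths(centers_gl) >=
                                                  cfg$kde$min_group]]
      if (length(ok) >= cfg$kde$min_group) {
        sel <- match(ok, sp$geno$ids)
        kc <- kde_contours(sp$coords[sel, , drop = FALSE],
                           groups = sres$centers$center[
                             match(ok, sres$centers$id)],
                           levels = cfg$kde$levels,
                           min_group = cfg$kde$min_group)
        kde_to_geojson(kc, file.path(out_dir, "kde_contours.geojson"))
      }
      NULL
    })
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "sibpop",
    version = as.character(utils::packageVersion("sibpop")),
    config = cfg,
    seeds = list(root = cfg$seed,
                 simulate = derive_seed(cfg$seed, "simulate"),
                 thin = derive_seed(cfg$seed, "thin"),
                 sibp = derive_seed(cfg$seed, "sibp"),
                 correlog = derive_seed(cfg$seed, "correlog")),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))),
    durations_s = durations,
    total_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  names(manifest$checksums) <- files
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
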