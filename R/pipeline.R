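#' Read a cohort back from plain-text files
#'
#' Inverse of [write_cohort()]: rebuilds the cohort container (strain
#' metadata, fingerprints, titrations, standard curves) from a directory of
#' CSVs, e.g. for real assay data laid out in the same format.
#'
#' @param dir Directory holding `strains.csv`, `profiles.csv`,
#'   `titrations.csv`, `blank.csv`, `standards_protein.csv`,
#'   `standards_sugar.csv`.
#' @return A list of class `cohort` (without `truth`).
#' @export
read_cohort <- function(dir) {
  need <- c("strains.csv", "profiles.csv", "titrations.csv", "blank.csv",
            "standards_protein.csv", "standards_sugar.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("cohort directory is missing: ", paste(missing, collapse = ", "))
  }
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  pstd <- rd("standards_protein.csv")
  sstd <- rd("standards_sugar.csv")
  structure(list(
    strains = rd("strains.csv"),
    profiles = read_profiles(file.path(dir, "profiles.csv")),
    titrations = rd("titrations.csv"),
    blank = rd("blank.csv"),
    protein_curve = standard_curve(pstd$concentration, pstd$absorbance),
    sugar_curve = standard_curve(sstd$concentration, sstd$absorbance),
    standards = list(protein = pstd, sugar = sstd)
  ), class = "cohort")
}

#' Run configuration for the end-to-end workflow
#'
#' @param cohort Either a [cohort_config()] (synthetic run) or a path to a
#'   directory of cohort files in [write_cohort()] layout.
#' @param out_dir Output directory for all stage artifacts.
#' @param tolerance,optimization,threshold Fingerprint parameters.
#' @param n_perm,alpha,seed Stats parameters; `seed` drives the Mantel
#'   permutation stream (defaults to the cohort seed when synthetic).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort, out_dir,
                       tolerance = 0.005, optimization = 0.005,
                       threshold = 0.90, n_perm = 9999L, alpha = 0.05,
                       seed = NULL) {
  synthetic <- inherits(cohort, "cohort_config")
  if (!synthetic) {
    stopifnot(is.character(cohort), dir.exists(cohort))
  }
  if (is.null(seed)) seed <- if (synthetic) cohort$seed else 1L
  structure(list(cohort = cohort, out_dir = out_dir, synthetic = synthetic,
                 tolerance = tolerance, optimization = optimization,
                 threshold = threshold, n_perm = as.integer(n_perm),
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' All scalar fields of [run_config()] plus a nested `cohort:` block of
#' [cohort_config()] fields (synthetic runs) or a `cohort_dir:` path.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort_dir)) {
    y$cohort_dir
  } else {
    do.call(cohort_config, if (is.null(y$cohort)) list() else y$cohort)
  }
  args <- y[intersect(names(y), c("tolerance", "optimization", "threshold",
                                  "n_perm", "alpha", "seed"))]
  do.call(run_config, c(list(cohort = cohort, out_dir = y$out_dir), args))
}

stage_files_manifest <- function(paths) {
  paths <- paths[file.exists(paths)]
  lapply(stats::setNames(as.list(unname(tools::md5sum(paths))),
                         basename(paths)), identity)
}

flatten_report <- function(report) {
  props <- lapply(report$properties, function(r) {
    if (is.null(r)) return(NULL)
    list(
      five_numbers = list(sediment = as.list(r$five_numbers$sediment$five),
                          water = as.list(r$five_numbers$water$five)),
      wilcoxon = list(statistic = r$wilcoxon$statistic,
                      p = r$wilcoxon$p_value, method = r$wilcoxon$method),
      pgls = list(beta_habitat = unname(r$pgls$beta[2L]),
                  se = unname(r$pgls$se[2L]), t = unname(r$pgls$t[2L]),
                  p = unname(r$pgls$p[2L]), sigma2 = r$pgls$sigma2)
    )
  })
  corr <- lapply(report$correlations, function(cm) {
    list(n = cm$n, tau = as.data.frame(cm$tau), p = as.data.frame(cm$p))
  })
  fig4 <- lapply(report$hydrophobicity_eps_protein, function(k) {
    if (is.null(k)) NULL else list(tau = k$statistic, p = k$p_value, n = k$n1)
  })
  list(properties = props,
       wilcoxon_p_bh = as.list(report$wilcoxon_p_bh),
       correlations = corr,
       mantel = list(r = report$mantel$statistic, p = report$mantel$p_value,
                     method = report$mantel$method),
       hydrophobicity_eps_protein = fig4,
       alpha = report$alpha)
}

#' Run the full workflow: simulate, fingerprint, assays, stats
#'
#' Executes the four stages in order under one configuration, writing every
#' stage artifact beneath `config$out_dir` and a machine-readable
#' `manifest.json` recording per-stage status, output file MD5 hashes,
#' timings, seeds, and strains dropped along the way (band-less fingerprints,
#' non-representative duplicates, per-property failures). A stage failure is
#' recorded and all downstream stages are skipped. Re-running the same
#' configuration reproduces byte-identical tables.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly also written to
#'   `file.path(config$out_dir, "manifest.json")`. Element `ok` is `FALSE`
#'   when any stage failed.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(created = format(Sys.time(), tz = "UTC"),
                   seed = config$seed, stages = list(), ok = TRUE,
                   dropped_strains = list())
  results <- new.env(parent = emptyenv())

  stages <- list(
    simulate = function() {
      cdir <- file.path(out, "cohort")
      if (config$synthetic) {
        cohort <- generate_cohort(config$cohort)
        write_cohort(cohort, cdir)
      } else {
        cdir <- config$cohort
        cohort <- read_cohort(cdir)
      }
      results$cohort <- cohort
      results$cohort_dir <- cdir
      list(files = stage_files_manifest(
        file.path(cdir, c("strains.csv", "profiles.csv", "titrations.csv",
                          "blank.csv"))))
    },
    fingerprint = function() {
      dropped <- character()
      withCallingHandlers(
        S <- similarity_matrix(results$cohort$profiles,
                               tolerance = config$tolerance,
                               optimization = config$optimization),
        warning = function(w) {
          dropped <<- c(dropped, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      results$similarity <- S
      tree <- ape::as.phylo(upgma(S))
      sel <- select_distinct(S, threshold = config$threshold)
      results$representatives <- sel$representatives
      dup <- setdiff(rownames(S), sel$representatives)
      manifest$dropped_strains$duplicates <<- dup
      if (length(dropped)) manifest$dropped_strains$no_bands <<- dropped

      utils::write.csv(as.data.frame(unclass(S)),
                       file.path(out, "similarity.csv"))
      ape::write.tree(tree, file.path(out, "dendrogram.nwk"))
      writeLines(sel$representatives, file.path(out, "representatives.txt"))
      list(n_strains = nrow(S), n_representatives = length(sel$representatives),
           files = stage_files_manifest(
             file.path(out, c("similarity.csv", "dendrogram.nwk",
                              "representatives.txt"))))
    },
    assays = function() {
      tab <- build_property_table(results$cohort)
      tab$phylotype <- vapply(seq_len(nrow(results$cohort$strains)),
        function(i) {
          s <- results$cohort$strains[i, ]
          assign_phylotype(marker_profile(s$arpA, s$chuA, s$yjaA, s$tspE4,
                                          s$group_c, s$group_e))
        }, character(1))
      tab <- tab[tab$strain_id %in% results$representatives, , drop = FALSE]
      results$properties <- tab
      utils::write.csv(tab, file.path(out, "properties.csv"),
                       row.names = FALSE)
      list(n_strains = nrow(tab),
           files = stage_files_manifest(file.path(out, "properties.csv")))
    },
    stats = function() {
      tab <- results$properties
      S <- results$similarity[tab$strain_id, tab$strain_id]
      report <- habitat_report(tab, S, n_perm = config$n_perm,
                               seed = config$seed, alpha = config$alpha)
      flat <- flatten_report(report)
      jsonlite::write_json(flat, file.path(out, "report.json"),
                           digits = NA, auto_unbox = TRUE, pretty = TRUE,
                           na = "null")
      utils::write.csv(as.data.frame(report$correlations$all$tau),
                       file.path(out, "table1.csv"))
      f3 <- do.call(rbind, lapply(names(report$properties), function(p) {
        r <- report$properties[[p]]
        if (is.null(r)) return(NULL)
        data.frame(property = p,
                   habitat = c("sediment", "water"),
                   rbind(r$five_numbers$sediment$five,
                         r$five_numbers$water$five),
                   wilcoxon_p = r$wilcoxon$p_value,
                   pgls_beta = unname(r$pgls$beta[2L]),
                   pgls_p = unname(r$pgls$p[2L]))
      }))
      utils::write.csv(f3, file.path(out, "figure3_summary.csv"),
                       row.names = FALSE)
      f4 <- results$properties[, c("strain_id", "habitat", "hydrophobicity",
                                   "eps_protein")]
      utils::write.csv(f4, file.path(out, "figure4_scatter.csv"),
                       row.names = FALSE)
      results$report <- report
      list(mantel_r = report$mantel$statistic,
           mantel_p = report$mantel$p_value,
           files = stage_files_manifest(
             file.path(out, c("report.json", "table1.csv",
                              "figure3_summary.csv", "figure4_scatter.csv"))))
    }
  )

  skip <- FALSE
  for (nm in names(stages)) {
    if (skip) {
      manifest$stages[[nm]] <- list(status = "skipped")
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(stages[[nm]](), error = function(e) e)
    elapsed <- round(proc.time()[["elapsed"]] - t0, 3)
    if (inherits(res, "error")) {
      manifest$stages[[nm]] <- list(status = "failed",
                                    error = conditionMessage(res),
                                    seconds = elapsed)
      manifest$ok <- FALSE
      skip <- TRUE
    } else {
      manifest$stages[[nm]] <- c(list(status = "completed",
                                      seconds = elapsed), res)
    }
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  manifest$report <- if (!is.null(results$report)) results$report
  manifest$properties <- if (!is.null(results$properties)) results$properties
  invisible(manifest)
}

#' Small end-to-end demonstration run
#'
#' Generates a 12 + 12 strain synthetic cohort and runs every stage;
#' completes in well under a minute.
#'
#' @param out_dir Output directory.
#' @param seed Seed.
#' @return The run manifest, invisibly.
#' @export
run_demo <- function(out_dir = tempfile("colisurf_demo"), seed = 1L) {
  cfg <- run_config(
    cohort_config(n_sediment = 12L, n_water = 12L, seed = seed),
    out_dir = out_dir, n_perm = 999L, seed = seed
  )
  run_all(cfg)
}
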