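#' Validate an analysis configuration
#'
#' A configuration is a named list (or YAML file) describing one or
#' two labeled conditions (e.g. wild-type vs mutant) and the stages to
#' run on each. Recognized stages: "cv" (collective variables), "ss"
#' (secondary structure), "interactions", "fes" (free-energy surface,
#' requires "cv"), "cd", "sec".
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list (class `"analysis_config"`) with
#'   defaults filled in.
#' @export
analysis_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(
    output_dir = "mutadyn_out", seed = 1L, temperature = 298.15,
    discard_ns = 50, window_ns = 10, threshold = 0.30,
    sg_order = 3L, sg_window = 9L,
    beta_region = 1532:1542, probe = 1611L, loop = 1545:1550,
    dt_ns = 0.4)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (length(config$beta_region) == 2L)
    config$beta_region <- seq(config$beta_region[1L], config$beta_region[2L])
  if (length(config$loop) == 2L)
    config$loop <- seq(config$loop[1L], config$loop[2L])
  if (is.null(config$stages) || length(config$stages) == 0L)
    stop("config must enable at least one stage")
  bad <- setdiff(config$stages, c("cv", "ss", "interactions", "fes", "cd", "sec"))
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("fes" %in% config$stages && !"cv" %in% config$stages)
    stop("the fes stage requires the cv stage")
  if (is.null(config$conditions) || length(config$conditions) == 0L)
    stop("config must define at least one condition")
  if (is.null(names(config$conditions)))
    stop("conditions must be named (e.g. wt, mutant)")
  class(config) <- c("analysis_config", "list")
  config
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Run one stage for one condition; returns a list of result tables
# that were written under `dir`.
run_stage <- function(stage, cond, config, dir) {
  files <- character(0)
  out <- list()
  need_traj <- function() {
    if (is.null(cond$trajectory)) stop("stage needs a 'trajectory' input")
    read_trajectory(cond$trajectory, dt = config$dt_ns)
  }
  if (stage == "cv") {
    traj <- need_traj()
    b <- beta_rmsd(traj, beta_rmsd_config(region = config$beta_region))
    d <- probe_loop_distance(traj, distance_config(probe = config$probe,
                                                   loop = config$loop))
    tab <- data.frame(frame = seq_len(nrow(b)), time_ns = b$time,
                      beta_rmsd = b$value, distance_A = d$value)
    files <- write_tsv(tab, file.path(dir, "cv.tsv"))
    out$cv <- tab
  } else if (stage == "ss") {
    traj <- need_traj()
    pr <- ss_probability(traj)
    files <- c(write_tsv(pr$table, file.path(dir, "ss_probability.tsv")),
               write_tsv(pr$replica, file.path(dir, "ss_composition.tsv")))
    out$ss <- pr
  } else if (stage == "interactions") {
    traj <- need_traj()
    rec <- interaction_probability(traj, config$probe)
    kept <- filter_interactions(rec, config$threshold)
    tab <- data.frame(Type = kept$type,
                      Residue = paste0(.aa3to1[kept$partner_resid], kept$partner),
                      `Probability (%)` = round(100 * kept$probability),
                      check.names = FALSE)
    files <- c(write_tsv(rec, file.path(dir, "interactions_all.tsv")),
               write_tsv(tab, file.path(dir, "interactions_filtered.tsv")))
    out$interactions <- tab
  } else if (stage == "fes") {
    cvtab <- utils::read.table(file.path(dir, "cv.tsv"), header = TRUE, sep = "\t")
    b <- cv_series("beta_rmsd", "", cvtab$time_ns, cvtab$beta_rmsd)
    d <- cv_series("distance", "A", cvtab$time_ns, cvtab$distance_A)
    stack <- block_histograms(b, d, discard_ns = config$discard_ns,
                              window_ns = config$window_ns)
    fes <- free_energy_surface(stack, config$temperature)
    grid <- expand.grid(beta_rmsd = fes$mid1, distance_A = fes$mid2)
    grid$F_kj_mol <- as.numeric(fes$F)
    grid$error_kj_mol <- as.numeric(fes$error)
    p1 <- project_1d(stack, 1L, config$temperature)
    p2 <- project_1d(stack, 2L, config$temperature)
    files <- c(write_tsv(grid, file.path(dir, "fes_2d.tsv")),
               write_tsv(p1, file.path(dir, "fes_1d_beta.tsv")),
               write_tsv(p2, file.path(dir, "fes_1d_distance.tsv")))
    out$fes <- list(surface = fes, beta = p1, distance = p2)
  } else if (stage == "cd") {
    if (is.null(cond$cd)) stop("stage needs a 'cd' input block")
    spectra <- lapply(cond$cd$spectra, read_cd_spectrum)
    baseline <- if (!is.null(cond$cd$baseline)) read_cd_spectrum(cond$cd$baseline)
    avg <- average_and_correct(spectra, baseline)
    if (attr(avg, "unit") == "mdeg") avg <- to_mre(avg)
    sm <- smooth_spectrum(avg, config$sg_order, config$sg_window)
    basis_dirs <- cond$cd$basis_dir %||% config$basis_dir
    cands <- lapply(basis_dirs, read_cd_basis)
    sel <- select_basis(sm, cands)
    three <- group_classes(sel$fit$fractions, sel$best)
    res <- data.frame(class = names(three), fraction = as.numeric(three),
                      basis = sel$best$name, rmsd_kmre = sel$fit$rmsd_kmre)
    files <- c(write_tsv(data.frame(wavelength = sm$wavelength,
                                    mre = sm$value),
                         file.path(dir, "cd_processed.tsv")),
               write_tsv(res, file.path(dir, "cd_fractions.tsv")))
    out$cd <- res
  } else if (stage == "sec") {
    if (is.null(cond$sec)) stop("stage needs a 'sec' input block")
    std <- read_standards(cond$sec$standards)
    cal <- fit_calibration(std)
    chrom <- read_chromatogram(cond$sec$chromatogram)
    pk <- detect_peaks(chrom)
    mw <- apparent_mw(pk$volume, cal)
    pk$mw_kda <- mw$mw_kda
    pk$extrapolated <- mw$extrapolated
    if (!is.null(cond$sec$monomer_mw)) {
      ord <- lapply(pk$mw_kda, oligomer_order, monomer_mw = cond$sec$monomer_mw)
      pk$ratio <- vapply(ord, `[[`, numeric(1L), "ratio")
      pk$order <- vapply(ord, `[[`, integer(1L), "order")
    }
    files <- write_tsv(pk, file.path(dir, "sec_peaks.tsv"))
    out$sec <- pk
  }
  list(tables = out, files = files)
}

#' Run the configured analysis pipeline
#'
#' Executes each enabled stage for each labeled condition, writing
#' per-stage TSV tables, a manifest with input/output checksums, and a
#' machine-readable JSON summary under the output directory. Stage
#' order is fixed (cv, ss, interactions, fes, then cd, sec). A stage
#' failure aborts the run with the stage name and cause; outputs
#' produced so far are retained next to a FAILED marker file.
#'
#' @param config A list, YAML path, or [analysis_config()] object.
#' @return Invisibly, a list with per-condition stage tables and the
#'   paths of the report files.
#' @export
run_pipeline <- function(config) {
  config <- if (inherits(config, "analysis_config")) config else analysis_config(config)
  ord <- c("cv", "ss", "interactions", "fes", "cd", "sec")
  stages <- ord[ord %in% config$stages]
  root <- config$output_dir
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list()
  for (cname in names(config$conditions)) {
    cond <- config$conditions[[cname]]
    cdir <- file.path(root, cname)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    for (stage in stages) {
      res <- tryCatch(
        run_stage(stage, cond, config, cdir),
        error = function(e) {
          writeLines(sprintf("FAILED at stage '%s' (condition '%s'): %s",
                             stage, cname, conditionMessage(e)),
                     file.path(root, "FAILED"))
          stop(sprintf("stage '%s' failed for condition '%s': %s",
                       stage, cname, conditionMessage(e)), call. = FALSE)
        })
      results[[cname]][[stage]] <- res$tables
      for (f in res$files)
        manifest[[length(manifest) + 1L]] <-
          list(condition = cname, stage = stage, file = f,
               md5 = unname(tools::md5sum(f)))
    }
  }
  # juxtapose interaction fingerprints across conditions
  if ("interactions" %in% stages && length(results) > 1L) {
    cmp <- do.call(rbind, lapply(names(results), function(cn) {
      t <- results[[cn]]$interactions$interactions
      if (is.null(t) || nrow(t) == 0L) return(NULL)
      cbind(condition = cn, t)
    }))
    if (!is.null(cmp)) write_tsv(cmp, file.path(root, "interactions_comparison.tsv"))
  }
  summary <- list(
    config = unclass(config)[setdiff(names(config), "conditions")],
    conditions = names(config$conditions),
    stages = stages,
    manifest = manifest)
  jsonlite::write_json(summary, file.path(root, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results,
                 summary_path = file.path(root, "summary.json")))
}
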