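# Orchestration: structures in, metrics and affinity tables out.
# A run config is a plain list (or YAML file) with `structures`,
# `biophysics`, shared thresholds, and an output directory.

#' Read and validate a run configuration
#'
#' @param config A list, or path to a YAML file. Recognized top-level
#'   fields: `structures` (list of entries with `path` or `model`,
#'   `kinase` or `emap`, `state`, optional `chain_roles`), `biophysics`
#'   (list of entries with `path` or `data`, `model` in
#'   itc/dsf/spr/ic50, `inhibitor`, `state`), `cutoff`, `link_threshold`,
#'   `out_dir`, `seed`, `element_config` (YAML overriding element maps).
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$cutoff <- config$cutoff %||% 4.0
  config$link_threshold <- config$link_threshold %||% 4.5
  config$structures <- config$structures %||% list()
  config$biophysics <- config$biophysics %||% list()
  states <- c("cyclin_free", "cyclin_bound")
  for (e in config$structures) {
    if (!is.null(e$state) && !e$state %in% states) {
      stop("structure state '", e$state, "' not in {",
           paste(states, collapse = ", "), "}", call. = FALSE)
    }
    if (!is.null(e$path) && is.null(e$model) && !file.exists(e$path)) {
      stop("structure path does not exist: ", e$path, call. = FALSE)
    }
  }
  for (e in config$biophysics) {
    if (!is.null(e$path) && is.null(e$data) && !file.exists(e$path)) {
      stop("biophysics path does not exist: ", e$path, call. = FALSE)
    }
    if (is.null(e$model) || !e$model %in% c("itc", "dsf", "spr", "ic50")) {
      stop("biophysics entry needs model in {itc, dsf, spr, ic50}",
           call. = FALSE)
    }
  }
  class(config) <- c("run_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_structure_entry <- function(entry, config) {
  model <- if (!is.null(entry$model)) {
    entry$model
  } else {
    roles <- unlist(entry$chain_roles) %||% NULL
    read_structure(entry$path, chain_roles = roles)
  }
  if (!any(model$chain_roles == "kinase")) {
    kin_chain <- entry$chain %||% sort(unique(model$atoms$chain_id))[1L]
    model$chain_roles[kin_chain] <- "kinase"
  }
  emap <- if (!is.null(entry$emap)) {
    entry$emap
  } else if (!is.null(config$element_config)) {
    element_map_from_config(config$element_config, entry$kinase)
  } else {
    default_element_map(entry$kinase)
  }
  list(model = model, emap = emap,
       label = entry$label %||% model$identifier)
}

#' Structural comparison report
#'
#' Per structure: inter-lobe contact census, R- and C-spine assessments,
#' and P-loop class; across structures: the contact-count ranking
#' ([compare_states()]) and a pairwise C-alpha superposition RMSD matrix.
#' Failures on a single structure are recorded and skipped, never fatal.
#'
#' @param config A [read_run_config()] input (list or YAML path).
#' @return Report list (`per_structure`, `ranking`, `rmsd_matrix`,
#'   `failures`); when `config$out_dir` is set, also written as
#'   `structural_report.tsv` and `structural_report.json`.
#' @export
run_structural_report <- function(config) {
  config <- read_run_config(config)
  if (length(config$structures) == 0L) {
    stop("config contains no structure entries", call. = FALSE)
  }
  entries <- list()
  failures <- list()
  for (e in config$structures) {
    res <- tryCatch(resolve_structure_entry(e, config), error = identity)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(entry = e$label %||% e$path, error = conditionMessage(res))
    } else {
      entries[[res$label]] <- res
    }
  }
  per_structure <- list()
  censuses <- list()
  for (label in names(entries)) {
    en <- entries[[label]]
    row <- list(label = label)
    census <- tryCatch(contact_census(en$model, en$emap,
                                      cutoff = config$cutoff),
                       error = identity)
    if (inherits(census, "error")) {
      failures[[length(failures) + 1L]] <-
        list(entry = label, error = conditionMessage(census))
    } else {
      censuses[[label]] <- census
      row$total_contacts <- census$total_contacts
    }
    for (sp in c("R", "C")) {
      a <- tryCatch(assess_spine(en$model, en$emap, spine = sp,
                                 link_threshold = config$link_threshold),
                    error = identity)
      row[[paste0(tolower(sp), "_spine_assembled")]] <-
        if (inherits(a, "error")) NA else a$assembled
    }
    pl <- tryCatch(classify_ploop(en$model, en$emap), error = identity)
    row$ploop <- if (inherits(pl, "error")) NA_character_ else pl$label
    per_structure[[label]] <- row
  }
  ranking <- if (length(censuses) >= 2L) compare_states(censuses) else NULL
  labels <- names(entries)
  rmsd <- matrix(NA_real_, length(labels), length(labels),
                 dimnames = list(labels, labels))
  diag(rmsd) <- 0
  if (length(labels) >= 2L) {
    for (i in seq_along(labels)) for (j in seq_along(labels)) {
      if (i < j) {
        sp <- tryCatch(
          superpose(entries[[i]]$model, entries[[j]]$model),
          error = identity)
        if (!inherits(sp, "error")) {
          rmsd[i, j] <- rmsd[j, i] <- sp$rmsd
        }
      }
    }
  }
  report <- list(per_structure = per_structure, ranking = ranking,
                 rmsd_matrix = rmsd, failures = failures,
                 cutoff = config$cutoff)
  if (!is.null(config$out_dir)) {
    write_structural_report(report, config$out_dir)
  }
  report
}

write_structural_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(report$per_structure, function(r) {
    data.frame(label = r$label,
               total_contacts = r$total_contacts %||% NA,
               r_spine_assembled = r$r_spine_assembled %||% NA,
               c_spine_assembled = r$c_spine_assembled %||% NA,
               ploop = r$ploop %||% NA_character_)
  }))
  utils::write.table(rows, file.path(out_dir, "structural_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  json <- list(
    cutoff = report$cutoff,
    per_structure = report$per_structure,
    ranking = report$ranking,
    rmsd_matrix = report$rmsd_matrix,
    failures = report$failures)
  jsonlite::write_json(json, file.path(out_dir, "structural_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       matrix = "rowmajor", force = TRUE)
  invisible(report)
}

read_biophysics_entry <- function(entry) {
  if (!is.null(entry$data)) return(entry$data)
  df <- utils::read.csv(entry$path, stringsAsFactors = FALSE)
  switch(entry$model,
    itc = df,
    dsf = stats::setNames(df, c("temperature_c", "fluorescence")),
    spr = stats::setNames(df, c("concentration", "response")),
    ic50 = {
      names(df) <- c("concentration", "activity")
      df$concentration <- df$concentration * 1000  # uM on disk, nM in memory
      df
    })
}

#' Affinity and thermodynamics report
#'
#' Runs the fitter matching each biophysics entry (`itc`, `dsf`, `spr`,
#' `ic50`), assembles the inhibitor-by-state affinity table with fold
#' columns, and computes thermodynamic signatures for ITC entries.
#'
#' @param config A [read_run_config()] input. Per-entry extras: ITC
#'   entries may carry `schedule` (an [injection_schedule()]) when their
#'   CSV departs from the default protocol; `fold_pairs` (named list of
#'   state pairs) configures the fold columns.
#' @return Report list (`fits`, `affinity_table`, `signatures`,
#'   `failures`); written to `out_dir` as `affinity_report.{tsv,json}`
#'   when set.
#' @export
run_affinity_report <- function(config) {
  config <- read_run_config(config)
  fits <- list()
  failures <- list()
  signatures <- list()
  for (e in config$biophysics) {
    lab <- paste(e$inhibitor %||% "?", e$state %||% "?", e$model, sep = "/")
    out <- tryCatch({
      dat <- read_biophysics_entry(e)
      switch(e$model,
        itc = {
          sch <- e$schedule %||% injection_schedule(
            injection_volumes_ul = dat$injection_volume_uL)
          iso <- structure(
            list(schedule = sch, heats = dat$heat_ucal,
                 molar_ratio = NULL, details = NULL),
            class = "itc_isotherm")
          iso <- rebuild_isotherm(iso)
          fit <- fit_one_site(iso)
          fit$meta$temperature_k <- sch$temperature_k
          fit
        },
        dsf = fit_boltzmann_melt(dat),
        spr = fit_spr_affinity(dat),
        ic50 = fit_ic50(dat))
    }, error = identity)
    if (inherits(out, "error")) {
      failures[[length(failures) + 1L]] <-
        list(entry = lab, error = conditionMessage(out))
    } else {
      fits[[lab]] <- c(list(inhibitor = e$inhibitor, state = e$state,
                            model = e$model), list(fit = out))
    }
  }
  for (lab in names(fits)) {
    f <- fits[[lab]]
    if (f$model == "itc" && is.na(f$fit$meta$kd_bound)) {
      signatures[[lab]] <- thermo_signature(
        f$fit$params[["kd"]], f$fit$params[["dh"]],
        f$fit$meta$temperature_k %||% 303.15)
    }
  }
  kd_rows <- do.call(rbind, lapply(fits, function(f) {
    if (!f$model %in% c("itc", "spr")) return(NULL)
    kd <- f$fit$params[["kd"]]
    if (f$model == "itc") kd <- kd * 1e9   # molar -> nM, table convention
    data.frame(inhibitor = f$inhibitor, state = f$state, kd = kd,
               se = if (f$model == "itc") f$fit$se[["kd"]] * 1e9
                    else f$fit$se[["kd"]],
               kd_bound = if (f$model == "itc" &&
                              !is.na(f$fit$meta$kd_bound))
                            f$fit$meta$kd_bound * 1e9
                          else f$fit$meta$kd_bound %||% NA_real_)
  }))
  affinity_table <- if (!is.null(kd_rows) && nrow(kd_rows) > 0L) {
    build_affinity_table(kd_rows, fold_pairs = config$fold_pairs %||% list())
  } else {
    data.frame(inhibitor = character(0))
  }
  report <- list(fits = fits, affinity_table = affinity_table,
                 signatures = signatures, failures = failures)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(affinity_table,
                       file.path(config$out_dir, "affinity_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(affinity_table = affinity_table,
           signatures = signatures,
           failures = failures),
      file.path(config$out_dir, "affinity_report.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE, force = TRUE)
  }
  report
}

# Recompute molar ratios and concentration bookkeeping for an isotherm
# loaded from disk (heats observed, composition implied by the schedule).
rebuild_isotherm <- function(iso) {
  sch <- iso$schedule
  sim <- simulate_itc(one_site_params(kd = 1e-6, dh = -1), sch)
  iso$molar_ratio <- sim$molar_ratio
  iso$details <- data.frame(
    total_titrand = sim$details$total_titrand,
    total_titrant = sim$details$total_titrant,
    bound = NA_real_)
  iso
}

#' Validate a report bundle's shape
#'
#' Checks the presence and types of the required fields of a structural
#' or affinity report (the packaged report contract).
#'
#' @param report A report list from [run_structural_report()] or
#'   [run_affinity_report()].
#' @param kind `"structural"` or `"affinity"`.
#' @return `TRUE` invisibly; errors describe the first violated field.
#' @export
validate_report_bundle <- function(report, kind = c("structural",
                                                    "affinity")) {
  kind <- match.arg(kind)
  need <- if (kind == "structural") {
    c("per_structure", "rmsd_matrix", "failures", "cutoff")
  } else {
    c("fits", "affinity_table", "signatures", "failures")
  }
  for (f in need) {
    if (!f %in% names(report)) stop("report is missing field '", f, "'",
                                    call. = FALSE)
  }
  if (kind == "structural" && !is.matrix(report$rmsd_matrix)) {
    stop("rmsd_matrix must be a matrix", call. = FALSE)
  }
  if (kind == "affinity" && !is.data.frame(report$affinity_table)) {
    stop("affinity_table must be a data frame", call. = FALSE)
  }
  invisible(TRUE)
}
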