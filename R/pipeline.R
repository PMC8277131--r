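#' Pipeline configuration
#'
#' All thresholds of the screening workflow in one serializable object.
#' The defaults reproduce the standard screening parameters: S/N > 3,
#' minimum peak intensity 3e4, at least 3 consecutive scans, mass
#' tolerance < 3 ppm, isotope-intensity tolerance +/- 30 percent, blank
#' ratio 3, library match threshold 85 percent.
#'
#' @param mode analysis mode: \code{"pm_negative"} (particulate matter,
#'   negative ionization), \code{"water_negative"} (allows Cl in
#'   formulas) or \code{"positive"}
#' @param min_sn,min_intensity,min_scans peak-detection gates
#' @param tol_ppm formula mass tolerance (ppm, exclusive)
#' @param iso_tol isotope-pattern relative tolerance
#' @param blank_ratio minimum sample/blank area ratio
#' @param min_score MS2 library match threshold (percent)
#' @param rt_tol co-elution / matching RT tolerance (min)
#' @param mz_tol_ppm feature-matching m/z tolerance (ppm)
#' @param adduct_mode \code{"independent"} or \code{"vendor_compat"}
#'   (see \code{\link{group_adducts}})
#' @param preferred preferred reported adduct (NULL for the polarity
#'   default)
#' @param align align retention times across sample runs
#' @param carbon_bins carbon-number bins for
#'   \code{\link{group_composition}}
#' @param source_categories named character vector: compound -> source
#'   category
#' @param rt_window level-1 RT agreement window (min)
#' @param seed seed echoed into the run log
#' @return an \code{nts_config}
#' @export
pipeline_config <- function(mode = c("pm_negative", "water_negative",
                                     "positive"),
                            min_sn = 3, min_intensity = 3e4, min_scans = 3,
                            tol_ppm = 3, iso_tol = 0.30, blank_ratio = 3,
                            min_score = 85, rt_tol = 0.1, mz_tol_ppm = 5,
                            adduct_mode = "independent", preferred = NULL,
                            align = FALSE,
                            carbon_bins = .default_carbon_bins,
                            source_categories = NULL, rt_window = 0.3,
                            seed = 1) {
  mode <- match.arg(mode)
  polarity <- if (mode == "positive") "positive" else "negative"
  limits <- switch(mode,
                   pm_negative = element_limits("negative_pm"),
                   water_negative = element_limits("negative_water"),
                   positive = element_limits("positive"))
  structure(list(mode = mode, polarity = polarity, limits = limits,
                 min_sn = min_sn, min_intensity = min_intensity,
                 min_scans = min_scans, tol_ppm = tol_ppm,
                 iso_tol = iso_tol, blank_ratio = blank_ratio,
                 min_score = min_score, rt_tol = rt_tol,
                 mz_tol_ppm = mz_tol_ppm, adduct_mode = adduct_mode,
                 preferred = preferred, align = align,
                 carbon_bins = carbon_bins,
                 source_categories = source_categories,
                 rt_window = rt_window, seed = seed),
            class = "nts_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config an \code{nts_config}
#' @param path file path
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$limits <- list(mode = config$limits$mode,
                   max = as.list(config$limits$max))
  x$schema_version <- 1
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  stopifnot(identical(x$schema_version, 1L) || identical(x$schema_version, 1))
  cfg <- pipeline_config(
    mode = x$mode, min_sn = x$min_sn, min_intensity = x$min_intensity,
    min_scans = x$min_scans, tol_ppm = x$tol_ppm, iso_tol = x$iso_tol,
    blank_ratio = x$blank_ratio, min_score = x$min_score,
    rt_tol = x$rt_tol, mz_tol_ppm = x$mz_tol_ppm,
    adduct_mode = x$adduct_mode,
    preferred = x$preferred,
    align = x$align, rt_window = x$rt_window, seed = x$seed)
  cfg
}

#' Run the full non-targeted screening pipeline
#'
#' Executes the workflow stages in fixed order: RT alignment (optional)
#' -> feature detection -> adduct grouping and artifact removal ->
#' blank subtraction -> molecular formula assignment (with erroneous
#' filtering and isotope verification) -> MS2 library screening and
#' confidence levels -> chemical metrics -> compositional groupings ->
#' optional quantification. Every stage's feature counts are logged so
#' that retained + removed = detected at each step. Deterministic for
#' fixed inputs and configuration.
#'
#' @param samples list of sample \code{nts_run}
#' @param blanks optional named list with elements \code{solvent} and/or
#'   \code{procedural} (each an \code{nts_run}); missing blanks
#'   downgrade to a warning
#' @param config an \code{\link{pipeline_config}}
#' @param library optional MS2 library (list of
#'   \code{nts_library_entry})
#' @param ms2_queries optional per-sample list of \code{nts_ms2} query
#'   spectra (outer list parallel to \code{samples})
#' @param calibrations optional named list of \code{nts_calibration}
#'   keyed by compound name
#' @param out_dir optional directory; when given, every intermediate
#'   table and a JSON run summary are written there
#' @return an \code{nts_result}: per-sample list of tables
#'   (\code{features, components, retained, assignments, metrics,
#'   grouped, identifications, quantified, removal_log}), plus
#'   \code{log} and \code{config}
#' @export
run_pipeline <- function(samples, blanks = list(),
                         config = pipeline_config(), library = NULL,
                         ms2_queries = NULL, calibrations = NULL,
                         out_dir = NULL) {
  stopifnot(length(samples) >= 1)
  for (r in samples) {
    if (r$polarity != config$polarity) {
      stop("polarity mismatch: run ", r$sample, " is ", r$polarity,
           " but config is ", config$polarity)
    }
  }
  if (!length(blanks)) {
    warning("no blank runs supplied; blank subtraction skipped")
  }
  log <- list(stage_order = c("align", "detect", "group_adducts",
                              "blank_subtract", "assign", "ms2_screen",
                              "metrics", "group"),
              config = unclass(config)[c("mode", "min_sn",
                                         "min_intensity", "min_scans",
                                         "tol_ppm", "iso_tol",
                                         "blank_ratio", "min_score",
                                         "adduct_mode", "seed")])
  if (config$align && length(samples) > 1) {
    al <- align_runs(samples)
    samples <- Map(apply_warp, samples, al$warps)
    log$alignment <- al$summary
  }
  blank_feats <- lapply(blanks, function(b) {
    detect_features(b, config$min_sn, config$min_intensity,
                    config$min_scans)
  })
  tab <- artifact_table(config$polarity, rt_tol = config$rt_tol,
                        mz_tol_ppm = config$mz_tol_ppm,
                        preferred = config$preferred)
  results <- list()
  for (si in seq_along(samples)) {
    run <- samples[[si]]
    feats <- detect_features(run, config$min_sn, config$min_intensity,
                             config$min_scans)
    grouped <- group_adducts(feats, tab, mode = config$adduct_mode)
    art <- remove_artifacts(grouped)
    bl <- blank_subtract(art$retained,
                         solvent_blank = blank_feats$solvent,
                         procedural_blank = blank_feats$procedural,
                         ratio_threshold = config$blank_ratio,
                         mz_tol_ppm = config$mz_tol_ppm,
                         rt_tol = config$rt_tol)
    retained <- bl$retained
    assignments <- do.call(rbind, lapply(seq_len(nrow(retained)),
                                         function(i) {
      species <- strsplit(retained$species_hypotheses[i], ";")[[1]]
      a <- assign_feature(
        retained$mz[i], species,
        iso_obs = c(retained$iso_a1[i], retained$iso_a2[i]),
        intensity = retained$intensity[i], limits = config$limits,
        tol_ppm = config$tol_ppm, iso_tol = config$iso_tol,
        floor = config$min_intensity)
      cbind(feature_id = retained$feature_id[i], a,
            rt = retained$rt[i], area = retained$area[i],
            stringsAsFactors = FALSE)
    }))
    if (is.null(assignments)) {
      assignments <- data.frame(feature_id = character(0))
    }
    # MS2 screening
    idents <- NULL
    queries <- if (!is.null(ms2_queries)) ms2_queries[[si]] else NULL
    if (!is.null(library) && !is.null(queries) &&
        nrow(assignments)) {
      rows <- list()
      for (i in seq_len(nrow(assignments))) {
        q <- NULL
        for (cand in queries) {
          if (abs(cand$precursor_mz - assignments$mz[i]) <=
              assignments$mz[i] * 10e-6 &&
              (is.na(cand$rt) ||
               abs(cand$rt - assignments$rt[i]) <= config$rt_window)) {
            q <- cand; break
          }
        }
        has_formula <- assignments$status[i] == "assigned"
        if (is.null(q)) {
          lvl <- assign_confidence(has_formula, has_ms2 = FALSE)
          rows[[length(rows) + 1]] <- data.frame(
            feature_id = assignments$feature_id[i],
            compound = NA_character_, score = NA_real_, level = lvl,
            stringsAsFactors = FALSE)
          next
        }
        hits <- search_library(q, library, min_score = config$min_score)
        top <- if (nrow(hits)) hits[1, ] else NULL
        lvl <- assign_confidence(
          has_formula, has_ms2 = TRUE,
          match_score = if (is.null(top)) NA_real_ else top$score,
          rt_deviation = if (is.null(top)) NA_real_ else top$rt_deviation,
          score_threshold = config$min_score,
          rt_window = config$rt_window)
        rows[[length(rows) + 1]] <- data.frame(
          feature_id = assignments$feature_id[i],
          compound = if (is.null(top)) NA_character_ else top$compound,
          score = if (is.null(top)) NA_real_ else top$score,
          level = lvl, stringsAsFactors = FALSE)
      }
      idents <- do.call(rbind, rows)
    }
    assigned <- assignments[!is.na(assignments$formula), , drop = FALSE]
    mets <- if (nrow(assigned)) {
      cbind(feature_id = assigned$feature_id,
            metric_table(assigned$formula))
    } else NULL
    grouped_tab <- if (nrow(assigned)) {
      ft <- data.frame(formula = assigned$formula, area = assigned$area)
      group_composition(ft, bins = config$carbon_bins,
                        sample = run$sample)
    } else NULL
    quantified <- NULL
    if (!is.null(calibrations) && !is.null(idents)) {
      hit <- idents[!is.na(idents$compound) &
                      idents$compound %in% names(calibrations), ,
                    drop = FALSE]
      if (nrow(hit)) {
        quantified <- do.call(rbind, lapply(seq_len(nrow(hit)),
                                            function(i) {
          area <- assignments$area[match(hit$feature_id[i],
                                         assignments$feature_id)]
          q <- quantify(area, calibrations[[hit$compound[i]]])
          data.frame(feature_id = hit$feature_id[i],
                     compound = hit$compound[i],
                     concentration = q$concentration, flag = q$flag,
                     stringsAsFactors = FALSE)
        }))
      }
    }
    counts <- c(detected = nrow(feats),
                isotope_removed = attr(feats, "n_isotope_removed"),
                components = nrow(art$retained),
                adduct_removed = nrow(art$removed),
                blank_removed = if (is.null(bl$removed)) 0L
                                else nrow(bl$removed),
                retained = nrow(retained),
                assigned = sum(assignments$status %in%
                                 c("assigned", "ambiguous")),
                identified = if (is.null(idents)) 0L
                             else sum(!is.na(idents$compound)))
    removal_log <- rbind(
      if (nrow(art$removed)) art$removed[, c("feature_id", "reason")],
      if (!is.null(bl$removed)) bl$removed[, c("feature_id", "reason")])
    results[[run$sample]] <- list(
      features = feats, components = grouped$components,
      retained = retained, assignments = assignments,
      identifications = idents, metrics = mets, grouped = grouped_tab,
      quantified = quantified, removal_log = removal_log,
      counts = counts)
  }
  log$counts <- lapply(results, `[[`, "counts")
  out <- structure(list(samples = results, log = log, config = config),
                   class = "nts_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(results)) {
      r <- results[[nm]]
      for (tb in c("features", "retained", "assignments", "metrics",
                   "grouped", "identifications", "quantified",
                   "removal_log")) {
        if (!is.null(r[[tb]]) && is.data.frame(r[[tb]]) &&
            nrow(r[[tb]])) {
          write_table(file.path(out_dir, sprintf("%s_%s.csv", nm, tb)),
                      r[[tb]])
        }
      }
    }
    jsonlite::write_json(
      list(config = log$config,
           counts = lapply(log$counts, as.list)),
      file.path(out_dir, "run_summary.json"), auto_unbox = TRUE,
      pretty = TRUE)
  }
  out
}

#' @export
print.nts_result <- function(x, ...) {
  cat("<ntscreen result>\n")
  for (nm in names(x$samples)) {
    cn <- x$samples[[nm]]$counts
    cat(sprintf(
      "  %s: detected %d, components %d, retained %d, assigned %d, identified %d\n",
      nm, cn[["detected"]], cn[["components"]], cn[["retained"]],
      cn[["assigned"]], cn[["identified"]]))
  }
  invisible(x)
}
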