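#' Group co-eluting ESI adducts/artifacts into components
#'
#' Features from one run and polarity that co-elute within the table's
#' RT tolerance and whose m/z values are consistent with one neutral
#' mass under the table's ion species are merged into a component. Each
#' seed feature (most intense first) is hypothesized to be one of the
#' species and the hypothesis explaining the most co-eluting members
#' wins (ties go to the preference order).
#'
#' Modes differ in how ungrouped features and non-primary seeds are
#' treated. \code{"vendor_compat"} replicates the documented limitation
#' of the commercial software: components are only seeded from the
#' primary adduct hypothesis (\code{[M+H]+} / \code{[M-H]-}), so a
#' compound observed exclusively as \code{[M+Na]+} is never recognized
#' as sodiated. \code{"independent"} seeds from every species in the
#' table and, for features that remain singletons in positive mode,
#' records the alternative adduct hypotheses so downstream formula
#' assignment can adjudicate.
#'
#' @param features feature data.frame (needs \code{feature_id, mz, rt,
#'   intensity, area})
#' @param table an \code{\link{artifact_table}}
#' @param mode \code{"independent"} or \code{"vendor_compat"}
#' @return list with \code{features} (input plus \code{component_id},
#'   \code{species}, \code{preferred}) and \code{components} (one row per
#'   component: id, n_members, preferred feature, neutral mass, rt,
#'   semicolon-joined \code{species_hypotheses} for assignment)
#' @export
group_adducts <- function(features, table,
                          mode = c("independent", "vendor_compat")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "nts_artifact_table"))
  ft <- features
  n <- nrow(ft)
  if (n == 0) {
    ft$component_id <- character(0)
    ft$species <- character(0)
    ft$preferred <- logical(0)
    return(list(features = ft,
                components = data.frame(component_id = character(0),
                                        n_members = integer(0),
                                        preferred_feature = character(0),
                                        neutral_mass = numeric(0),
                                        rt = numeric(0),
                                        species_hypotheses = character(0),
                                        stringsAsFactors = FALSE)))
  }
  ft$component_id <- NA_character_
  ft$species <- NA_character_
  ft$preferred <- FALSE
  sp_tab <- table$species
  labels <- names(sp_tab)
  pref <- table$preferred
  # species tried as the seed identity
  seed_labels <- if (mode == "vendor_compat") pref else labels
  assigned <- logical(n)
  comp <- list()
  for (s in order(-ft$intensity)) {
    if (assigned[s]) next
    best <- NULL
    for (seed_lab in seed_labels) {
      seed_sp <- sp_tab[[seed_lab]]
      if (seed_sp$n_m != 1) next  # a dimer is never the seed identity
      M <- ft$mz[s] - seed_sp$delta
      if (M <= 0) next
      members <- s
      member_lab <- seed_lab
      for (j in seq_len(n)) {
        if (j == s || assigned[j]) next
        if (abs(ft$rt[j] - ft$rt[s]) > table$rt_tol) next
        for (lab in labels) {
          spj <- sp_tab[[lab]]
          mz_th <- spj$n_m * M + spj$delta
          if (abs(ft$mz[j] - mz_th) <= ft$mz[j] * table$mz_tol_ppm * 1e-6) {
            members <- c(members, j)
            member_lab <- c(member_lab, lab)
            break
          }
        }
      }
      if (is.null(best) || length(members) > length(best$members)) {
        best <- list(members = members, labels = member_lab, M = M,
                     seed = seed_lab)
      }
    }
    if (is.null(best)) {
      best <- list(members = s, labels = pref, M = ft$mz[s] -
                     sp_tab[[pref]]$delta, seed = pref)
    }
    cid <- sprintf("C%04d", length(comp) + 1L)
    assigned[best$members] <- TRUE
    ft$component_id[best$members] <- cid
    ft$species[best$members] <- best$labels
    # elect the preferred member
    p <- if (pref %in% best$labels) {
      best$members[match(pref, best$labels)]
    } else {
      best$members[which.max(ft$intensity[best$members])]
    }
    ft$preferred[p] <- TRUE
    hyp <- ft$species[p]
    if (length(best$members) == 1 && mode == "independent" &&
        table$polarity == "positive") {
      # a lone positive-mode feature may really be sodiated/potassiated
      hyp <- unique(c(hyp, intersect(c("[M+Na]+", "[M+K]+"), labels)))
    }
    comp[[length(comp) + 1]] <- data.frame(
      component_id = cid, n_members = length(best$members),
      preferred_feature = ft$feature_id[p], neutral_mass = best$M,
      rt = ft$rt[p], species_hypotheses = paste(hyp, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(features = ft, components = do.call(rbind, comp))
}

#' Report only the preferred adduct of each component
#'
#' Collapses a grouped feature table to one row per component (the
#' elected preferred adduct); dropped members are logged with the
#' component and species they belonged to.
#'
#' @param grouped result of \code{\link{group_adducts}}
#' @return list with \code{retained} (one row per component, carrying
#'   \code{species_hypotheses}) and \code{removed} (log with
#'   \code{reason})
#' @export
remove_artifacts <- function(grouped) {
  ft <- grouped$features
  retained <- ft[ft$preferred, , drop = FALSE]
  retained <- merge(retained,
                    grouped$components[, c("component_id",
                                           "species_hypotheses")],
                    by = "component_id", sort = FALSE)
  removed <- ft[!ft$preferred, , drop = FALSE]
  if (nrow(removed)) {
    removed$reason <- sprintf("artifact_%s_of_%s", removed$species,
                              removed$component_id)
  } else {
    removed$reason <- character(0)
  }
  rownames(retained) <- rownames(removed) <- NULL
  list(retained = retained, removed = removed)
}

#' Subtract solvent- and procedural-blank artifacts
#'
#' A sample feature matching a blank feature by m/z (ppm tolerance) and
#' RT is removed unless its area reaches \code{ratio_threshold} times the
#' blank area; matched-but-retained features are annotated with the
#' sample/blank area ratio. Both blanks are applied sequentially
#' (solvent first), so a feature must beat the threshold against every
#' blank it matches. Features absent from both blanks pass unchanged.
#' The operation is idempotent: re-applying the same blanks removes
#' nothing more.
#'
#' @param sample sample feature data.frame
#' @param solvent_blank,procedural_blank blank feature data.frames (or
#'   \code{NULL})
#' @param ratio_threshold minimum sample/blank area ratio to survive a
#'   match
#' @param mz_tol_ppm,rt_tol matching tolerances
#' @return list with \code{retained} (annotated with
#'   \code{blank_ratio}, NA when unmatched) and \code{removed} (log with
#'   \code{reason, matched_blank, ratio})
#' @export
blank_subtract <- function(sample, solvent_blank = NULL,
                           procedural_blank = NULL, ratio_threshold = 3,
                           mz_tol_ppm = 5, rt_tol = 0.1) {
  retained <- sample
  retained$blank_ratio <- rep(NA_real_, nrow(retained))
  removed <- list()
  blanks <- list(solvent_blank = solvent_blank,
                 procedural_blank = procedural_blank)
  for (bname in names(blanks)) {
    bl <- blanks[[bname]]
    if (is.null(bl) || !nrow(bl) || !nrow(retained)) next
    keep <- logical(nrow(retained))
    for (i in seq_len(nrow(retained))) {
      hit <- which(abs(bl$mz - retained$mz[i]) <=
                     retained$mz[i] * mz_tol_ppm * 1e-6 &
                     abs(bl$rt - retained$rt[i]) <= rt_tol)
      if (!length(hit)) { keep[i] <- TRUE; next }
      ratio <- retained$area[i] / max(bl$area[hit])
      if (ratio >= ratio_threshold) {
        keep[i] <- TRUE
        retained$blank_ratio[i] <-
          min(retained$blank_ratio[i], ratio, na.rm = TRUE)
      } else {
        row <- retained[i, , drop = FALSE]
        row$reason <- "blank_artifact"
        row$matched_blank <- bname
        row$ratio <- ratio
        removed[[length(removed) + 1]] <- row
      }
    }
    retained <- retained[keep, , drop = FALSE]
  }
  removed <- if (length(removed)) do.call(rbind, removed) else NULL
  rownames(retained) <- NULL
  list(retained = retained, removed = removed)
}
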