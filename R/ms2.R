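#' MS2 fragmentation spectra
#'
#' @param fragments data.frame or matrix with columns \code{mz},
#'   \code{intensity}; stored sorted by m/z
#' @param precursor_mz precursor ion m/z
#' @param species ion species label (optional)
#' @param rt retention time in minutes (optional)
#' @param collision_energy optional collision energy
#' @return an \code{nts_ms2}
#' @export
ms2_spectrum <- function(fragments, precursor_mz, species = NA_character_,
                         rt = NA_real_, collision_energy = NA_real_) {
  fragments <- as.data.frame(fragments)
  stopifnot(all(c("mz", "intensity") %in% names(fragments)),
            all(fragments$intensity >= 0), precursor_mz > 0)
  fragments <- fragments[order(fragments$mz), , drop = FALSE]
  if (nrow(fragments) &&
      max(fragments$mz) > precursor_mz + 0.5) {
    stop("fragment m/z above precursor")
  }
  rownames(fragments) <- NULL
  structure(list(fragments = fragments, precursor_mz = precursor_mz,
                 species = species, rt = rt,
                 collision_energy = collision_energy),
            class = "nts_ms2")
}

#' @export
print.nts_ms2 <- function(x, ...) {
  cat(sprintf("<ms2> precursor %.4f (%s), %d fragments\n", x$precursor_mz,
              x$species, nrow(x$fragments)))
  invisible(x)
}

#' MS2 library entries
#'
#' @param name compound name
#' @param formula neutral formula (string or \code{nts_formula})
#' @param spectrum an \code{nts_ms2}
#' @param rt reference retention time of the authentic standard (min)
#' @param source_category optional pollutant-source label used by
#'   \code{\link{source_report}}
#' @return an \code{nts_library_entry}
#' @export
library_entry <- function(name, formula, spectrum, rt = NA_real_,
                          source_category = NA_character_) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(spectrum, "nts_ms2"))
  if (!is.na(spectrum$species)) {
    mz_th <- ion_mz(formula, spectrum$species)
    ppm <- abs(mz_th - spectrum$precursor_mz) / mz_th * 1e6
    if (ppm > 5) {
      stop(sprintf("precursor m/z inconsistent with %s as %s (%.1f ppm)",
                   format_formula(formula), spectrum$species, ppm))
    }
  }
  structure(list(name = name, formula = formula, spectrum = spectrum,
                 rt = rt, source_category = source_category),
            class = "nts_library_entry")
}

# greedy fragment pairing within tolerance: highest-intensity query
# fragments first, ties broken by smallest delta m/z
.match_fragments <- function(q, r, frag_tol) {
  qi <- order(-q$intensity)
  used <- logical(nrow(r))
  pairs <- matrix(numeric(0), ncol = 2)
  for (i in qi) {
    d <- abs(r$mz - q$mz[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= frag_tol) {
      used[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  pairs
}

#' Spectral similarity of two MS2 spectra
#'
#' 100 x the cosine between square-root-intensity vectors after greedy
#' fragment matching within \code{frag_tol}; unmatched fragments on
#' either side contribute to the norms only. Symmetric, deterministic,
#' scale-invariant in intensities; 100 iff the matched fragments are
#' proportional with no unmatched intensity, 0 when no fragments match.
#'
#' @param query,ref \code{nts_ms2} spectra
#' @param frag_tol fragment m/z matching tolerance in Da
#' @return percent score in [0, 100]
#' @export
spectral_similarity <- function(query, ref, frag_tol = 0.01) {
  stopifnot(inherits(query, "nts_ms2"), inherits(ref, "nts_ms2"))
  q <- query$fragments; r <- ref$fragments
  if (!nrow(q) || !nrow(r)) stop("empty spectrum")
  pairs <- .match_fragments(q, r, frag_tol)
  if (!nrow(pairs)) return(0)
  num <- sum(sqrt(q$intensity[pairs[, 1]]) * sqrt(r$intensity[pairs[, 2]]))
  den <- sqrt(sum(q$intensity)) * sqrt(sum(r$intensity))
  100 * num / den
}

#' Search an MS2 library
#'
#' Library entries whose precursor m/z is compatible with the query
#' within \code{precursor_tol_ppm} are scored with
#' \code{\link{spectral_similarity}}; hits at or above \code{min_score}
#' are returned ranked by descending score. The ranking is invariant to
#' the order of entries in the library.
#'
#' @param query an \code{nts_ms2}
#' @param library list of \code{nts_library_entry}
#' @param min_score minimum percent score to report
#' @param precursor_tol_ppm precursor matching tolerance
#' @param frag_tol fragment matching tolerance (Da)
#' @return data.frame of hits: \code{compound, formula, score,
#'   rt_deviation, library_rt}; zero rows when nothing qualifies
#' @export
search_library <- function(query, library, min_score = 85,
                           precursor_tol_ppm = 10, frag_tol = 0.01) {
  stopifnot(length(library) >= 1)
  rows <- list()
  for (entry in library) {
    dmz <- abs(entry$spectrum$precursor_mz - query$precursor_mz)
    if (dmz > query$precursor_mz * precursor_tol_ppm * 1e-6) next
    sc <- spectral_similarity(query, entry$spectrum, frag_tol)
    if (sc < min_score) next
    rows[[length(rows) + 1]] <- data.frame(
      compound = entry$name, formula = format_formula(entry$formula),
      score = sc,
      rt_deviation = if (is.na(entry$rt) || is.na(query$rt)) NA_real_
                     else query$rt - entry$rt,
      library_rt = entry$rt, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(compound = character(0), formula = character(0),
                      score = numeric(0), rt_deviation = numeric(0),
                      library_rt = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$compound), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Identification confidence level (1-5)
#'
#' The conventional five-level scale for high-resolution MS
#' identification: 5 = exact mass only; 4 = unambiguous molecular
#' formula, no MS2; 3 = formula plus recorded MS2 (tentative structure);
#' 2 = probable structure via a library spectral match at or above the
#' score threshold; 1 = level 2 plus retention-time agreement with the
#' authentic standard. Adding evidence never increases the numeric
#' level.
#'
#' @param has_formula unambiguous formula assigned?
#' @param has_ms2 MS2 spectrum recorded for the feature?
#' @param match_score library match score (percent) or \code{NA}
#' @param rt_deviation RT difference to the authentic standard (min) or
#'   \code{NA}
#' @param score_threshold minimum score counting as a library match
#' @param rt_window RT agreement window for level 1 (min)
#' @return integer level in 1:5
#' @export
assign_confidence <- function(has_formula, has_ms2 = FALSE,
                              match_score = NA_real_,
                              rt_deviation = NA_real_,
                              score_threshold = 85, rt_window = 0.3) {
  if (!has_formula) return(5L)
  matched <- !is.na(match_score) && match_score >= score_threshold
  if (matched && !is.na(rt_deviation) && abs(rt_deviation) <= rt_window) {
    return(1L)
  }
  if (matched) return(2L)
  if (has_ms2) return(3L)
  4L
}

# ---- MSP / MGF I/O -------------------------------------------------------

#' Read an MSP spectral library
#'
#' Minimal NIST-style MSP reader: \code{Name:}, \code{Formula:},
#' \code{PrecursorMZ:}, \code{RetentionTime:}, \code{Comment:},
#' \code{Num Peaks:} headers followed by whitespace-separated
#' mz/intensity pairs. Unknown headers are ignored.
#'
#' @param path file path
#' @return list of \code{nts_library_entry}
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  entries <- list()
  hdr <- list(); peaks <- list()
  flush <- function() {
    if (is.null(hdr$name)) return(invisible(NULL))
    pk <- do.call(rbind, peaks)
    sp <- ms2_spectrum(data.frame(mz = pk[, 1], intensity = pk[, 2]),
                       precursor_mz = hdr$precursor,
                       species = hdr$species %||% NA_character_,
                       rt = hdr$rt %||% NA_real_)
    entries[[length(entries) + 1]] <<-
      library_entry(hdr$name, hdr$formula, sp, rt = hdr$rt %||% NA_real_,
                    source_category = hdr$category %||% NA_character_)
    hdr <<- list(); peaks <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) { flush(); next }
    if (grepl("^[A-Za-z]", ln) && grepl(":", ln)) {
      key <- tolower(sub(":.*", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (key == "name") hdr$name <- val
      else if (key == "formula") hdr$formula <- val
      else if (key == "precursormz") hdr$precursor <- as.numeric(val)
      else if (key == "precursortype") hdr$species <- val
      else if (key == "retentiontime") hdr$rt <- as.numeric(val)
      else if (key == "comment") {
        m <- regmatches(val, regexec("category=([^ ;]+)", val))[[1]]
        if (length(m) == 2) hdr$category <- m[2]
      }
    } else {
      v <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
      if (length(v) >= 2 && !anyNA(v[1:2])) {
        peaks[[length(peaks) + 1]] <- v[1:2]
      }
    }
  }
  flush()
  entries
}

#' Write an MSP spectral library
#'
#' Round-trips with \code{\link{read_msp}}.
#'
#' @param entries list of \code{nts_library_entry}
#' @param path output file path
#' @export
write_msp <- function(entries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in entries) {
    cat(sprintf("Name: %s\n", e$name), file = con)
    cat(sprintf("Formula: %s\n", format_formula(e$formula)), file = con)
    cat(sprintf("PrecursorMZ: %.6f\n", e$spectrum$precursor_mz),
        file = con)
    if (!is.na(e$spectrum$species)) {
      cat(sprintf("PrecursorType: %s\n", e$spectrum$species), file = con)
    }
    if (!is.na(e$rt)) cat(sprintf("RetentionTime: %.4f\n", e$rt),
                          file = con)
    if (!is.na(e$source_category)) {
      cat(sprintf("Comment: category=%s\n", e$source_category), file = con)
    }
    cat(sprintf("Num Peaks: %d\n", nrow(e$spectrum$fragments)), file = con)
    for (i in seq_len(nrow(e$spectrum$fragments))) {
      cat(sprintf("%.6f %.1f\n", e$spectrum$fragments$mz[i],
                  e$spectrum$fragments$intensity[i]), file = con)
    }
    cat("\n", file = con)
  }
  invisible(path)
}

#' Read an MGF file of MS2 spectra
#'
#' Supports \code{BEGIN IONS}/\code{END IONS} blocks with
#' \code{TITLE=}, \code{PEPMASS=}, \code{RTINSECONDS=} headers.
#'
#' @param path file path
#' @return list of \code{nts_ms2} (names from TITLE where present)
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  inblock <- FALSE
  hdr <- list(); peaks <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "BEGIN IONS") {
      inblock <- TRUE; hdr <- list(); peaks <- list(); next
    }
    if (ln == "END IONS") {
      pk <- do.call(rbind, peaks)
      sp <- ms2_spectrum(data.frame(mz = pk[, 1], intensity = pk[, 2]),
                         precursor_mz = hdr$pepmass,
                         rt = (hdr$rtsec %||% NA_real_) / 60)
      if (!is.null(hdr$title)) {
        spectra[[hdr$title]] <- sp
      } else {
        spectra[[length(spectra) + 1]] <- sp
      }
      inblock <- FALSE; next
    }
    if (!inblock || !nzchar(ln)) next
    if (grepl("^TITLE=", ln)) hdr$title <- sub("^TITLE=", "", ln)
    else if (grepl("^PEPMASS=", ln)) {
      hdr$pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                         " ")[[1]][1])
    } else if (grepl("^RTINSECONDS=", ln)) {
      hdr$rtsec <- as.numeric(sub("^RTINSECONDS=", "", ln))
    } else if (grepl("^[0-9]", ln)) {
      v <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
      if (length(v) >= 2) peaks[[length(peaks) + 1]] <- v[1:2]
    }
  }
  spectra
}

#' Write MS2 spectra to MGF
#'
#' Round-trips with \code{\link{read_mgf}}.
#'
#' @param spectra named list of \code{nts_ms2}
#' @param path output file path
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nms <- names(spectra)
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    cat("BEGIN IONS\n", file = con)
    if (!is.null(nms) && nzchar(nms[i])) {
      cat(sprintf("TITLE=%s\n", nms[i]), file = con)
    }
    cat(sprintf("PEPMASS=%.6f\n", s$precursor_mz), file = con)
    if (!is.na(s$rt)) cat(sprintf("RTINSECONDS=%.2f\n", s$rt * 60),
                          file = con)
    for (j in seq_len(nrow(s$fragments))) {
      cat(sprintf("%.6f %.1f\n", s$fragments$mz[j],
                  s$fragments$intensity[j]), file = con)
    }
    cat("END IONS\n", file = con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
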