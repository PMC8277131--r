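#' Write a run as a scan-table CSV
#'
#' The plain-text fixture dialect: comment header lines carrying the
#' run metadata, then columns \code{scan_index, rt_min, mz, intensity}.
#' Round-trips losslessly with \code{\link{read_scan_table}}.
#'
#' @param run an \code{nts_run}
#' @param path output path
#' @export
write_scan_table <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# polarity: %s\n# sample: %s\n# role: %s\n# n_scans: %d\n",
              run$polarity, run$sample, run$role, length(run$rt)),
      file = con)
  cat("# rt_min_by_scan: ", paste(format(run$rt, digits = 12),
                                  collapse = ","), "\n",
      sep = "", file = con)
  cat("scan_index,rt_min,mz,intensity\n", file = con)
  cen <- run$centroids
  if (nrow(cen)) {
    utils::write.table(
      data.frame(scan_index = cen$scan,
                 rt_min = run$rt[cen$scan],
                 mz = cen$mz, intensity = cen$intensity),
      con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a scan-table CSV
#'
#' @param path file written by \code{\link{write_scan_table}} (or any
#'   CSV with columns \code{scan_index, rt_min, mz, intensity}; missing
#'   metadata defaults to a negative-mode sample)
#' @return an \code{nts_run}
#' @export
read_scan_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1]) else default
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("malformed scan table: no data section")
  if (!grepl("^scan_index", body[1])) {
    stop("malformed scan table: missing header row")
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("scan_index", "rt_min", "mz", "intensity")
  if (!all(need %in% names(df))) stop("malformed scan table columns")
  rt_meta <- get_meta("rt_min_by_scan", NA)
  if (!is.na(rt_meta)) {
    rt <- as.numeric(strsplit(rt_meta, ",")[[1]])
  } else {
    rt <- tapply(df$rt_min, df$scan_index, function(x) x[1])
    rt <- as.numeric(rt[order(as.integer(names(rt)))])
  }
  new_run(rt,
          data.frame(scan = df$scan_index, mz = df$mz,
                     intensity = df$intensity),
          polarity = get_meta("polarity", "negative"),
          sample = get_meta("sample", "sample"),
          role = get_meta("role", "sample"))
}

#' Write a run as mzML
#'
#' Minimal centroided MS1 mzML 1.1.0 with uncompressed 64-bit binary
#' arrays; readable by standard mzML parsers.
#'
#' @param run an \code{nts_run}
#' @param path output path
#' @export
write_mzml <- function(run, path) {
  enc <- function(x) {
    b <- jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                       endian = "little"))
    gsub("[\r\n ]", "", b)  # single-line base64; parsers reject wrapping
  }
  pol_cv <- if (run$polarity == "positive") {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
  }
  nscan <- length(run$rt)
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf(
'<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="1">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>
    </fileContent>
  </fileDescription>
  <softwareList count="1">
    <software id="ntscreen" version="0.1.0"/>
  </softwareList>
  <instrumentConfigurationList count="1">
    <instrumentConfiguration id="IC1"/>
  </instrumentConfigurationList>
  <dataProcessingList count="1">
    <dataProcessing id="DP1">
      <processingMethod order="1" softwareRef="ntscreen">
        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>
      </processingMethod>
    </dataProcessing>
  </dataProcessingList>
  <run id="%s" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="%d" defaultDataProcessingRef="DP1">
', run$sample, nscan), file = con)
  for (i in seq_len(nscan)) {
    sel <- run$centroids$scan == i
    mz <- run$centroids$mz[sel]
    it <- run$centroids$intensity[sel]
    b_mz <- enc(mz); b_it <- enc(it)
    cat(sprintf(
'      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">
        <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>
        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>
        %s
        <scanList count="1">
          <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>
          <scan>
            <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.8f" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
            <binary>%s</binary>
          </binaryDataArray>
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
            <binary>%s</binary>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>
', i - 1L, i, length(mz), pol_cv, run$rt[i], nchar(b_mz), b_mz,
      nchar(b_it), b_it), file = con)
  }
  cat("    </spectrumList>\n  </run>\n</mzML>\n", file = con)
  invisible(path)
}

#' Read a centroided mzML file
#'
#' Uses the mzR backend. Profile-mode spectra are rejected with a clear
#' error; only MS1 scans become the run's scan sequence.
#'
#' @param path mzML path
#' @param sample,role run labels
#' @return an \code{nts_run}
#' @export
read_mzml <- function(path, sample = basename(path), role = "sample") {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hd <- mzR::header(handle)
  hd1 <- hd[hd$msLevel == 1, , drop = FALSE]
  if (!nrow(hd1)) stop("no MS1 spectra in ", path)
  if (!is.null(hd1$centroided) && any(!hd1$centroided, na.rm = TRUE)) {
    stop("profile-mode spectra are not supported; centroid the data first")
  }
  pol <- "negative"
  if (!is.null(hd1$polarity) && any(hd1$polarity == 1)) pol <- "positive"
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  cen <- list()
  for (i in seq_len(nrow(hd1))) {
    m <- pk[[hd1$seqNum[i]]]
    if (is.null(dim(m)) || nrow(m) == 0) next
    cen[[length(cen) + 1]] <-
      data.frame(scan = i, mz = m[, 1], intensity = m[, 2])
  }
  centroids <- if (length(cen)) do.call(rbind, cen) else
    data.frame(scan = integer(0), mz = numeric(0), intensity = numeric(0))
  # scan start time: stored in seconds by mzR convention
  rt <- hd1$retentionTime / 60
  new_run(rt, centroids, polarity = pol, sample = sample, role = role)
}

#' Read a run from mzML or scan-table CSV
#'
#' @param path file path; dispatch on extension (\code{.mzML} /
#'   \code{.csv})
#' @param ... passed to the format reader
#' @return an \code{nts_run}
#' @export
read_run <- function(path, ...) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    read_mzml(path, ...)
  } else if (grepl("\\.(csv|txt)$", path, ignore.case = TRUE)) {
    read_scan_table(path)
  } else {
    stop("unrecognized run format: ", path)
  }
}

#' Write a result table as CSV
#' @param path output path
#' @param rows a data.frame
#' @export
write_table <- function(path, rows) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
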