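# File formats: TCK tractograms, NIfTI label volumes, per-vertex BOLD runs
# (TSV + JSON sidecar), connectivity CSV/JSON.

#' Write a streamline set as a TCK tractogram
#'
#' MRtrix track format: a text header (`mrtrix tracks`, `datatype`, `count`,
#' `file: . <offset>`, `END`), then little-endian float32 point triplets in mm
#' world coordinates, streamlines separated by a NaN triplet and the stream
#' terminated by an Inf triplet.
#'
#' @param set a `streamline_set` (or plain list of n x 3 matrices).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tck <- function(set, path) {
  sl <- if (inherits(set, "streamline_set")) set$streamlines else set
  n <- length(sl)
  body_head <- "mrtrix tracks\ndatatype: Float32LE\ncount: %d\nfile: . %d\nEND\n"
  # the offset appears inside the header, so fix it by iteration
  offset <- nchar(sprintf(body_head, n, 0))
  repeat {
    new_offset <- nchar(sprintf(body_head, n, offset))
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf(body_head, n, offset), con, eos = NULL)
  for (p in sl) {
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a TCK tractogram
#'
#' Honors the header's datatype (Float32LE/BE) and data offset; verifies the
#' `count` field against the streamlines actually present. Round-trips
#' bit-exactly with [write_tck()] for float32 data.
#'
#' @param path TCK file.
#' @return a `streamline_set` (ground-truth tags unknown: NA).
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # header is ASCII up to the END line
  end_pat <- as.raw(c(charToRaw("\nEND\n")))
  hdr_end <- find_bytes(raw, end_pat)
  if (is.na(hdr_end)) stopf("malformed TCK header in %s: no END line", path)
  hdr <- strsplit(rawToChar(raw[1:(hdr_end + length(end_pat) - 1)]), "\n")[[1]]
  if (!identical(hdr[1], "mrtrix tracks"))
    stopf("not a TCK file (missing magic line): %s", path)
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^", key, ":"), "", ln[1]))
  }
  datatype <- get_field("datatype")
  endian <- switch(datatype,
                   Float32LE = "little", Float32BE = "big",
                   stopf("unsupported TCK datatype '%s'", datatype))
  file_field <- get_field("file")
  offset <- suppressWarnings(as.integer(sub("^\\.\\s+", "", file_field)))
  if (is.na(offset)) stopf("malformed TCK 'file' field: '%s'", file_field)
  count_declared <- suppressWarnings(as.integer(get_field("count")))

  n_bytes <- length(raw) - offset
  if (n_bytes < 12 || n_bytes %% 4 != 0)
    stopf("truncated TCK data stream at byte offset %d", offset)
  vals <- readBin(raw[(offset + 1):length(raw)], "numeric", n_bytes / 4,
                  size = 4, endian = endian)
  if (length(vals) %% 3 != 0) stopf("TCK data stream is not a whole number of triplets")
  trip <- matrix(vals, ncol = 3, byrow = TRUE)

  inf_rows <- which(apply(trip, 1, function(r) all(is.infinite(r))))
  if (!length(inf_rows)) stopf("truncated TCK stream: missing Inf terminator")
  trip <- trip[seq_len(inf_rows[1] - 1), , drop = FALSE]
  is_sep <- apply(trip, 1, function(r) any(is.nan(r)))
  grp <- cumsum(c(0, is_sep[-length(is_sep)])) + 1
  sl <- if (nrow(trip)) {
    keep <- !is_sep
    split_idx <- split(which(keep), grp[keep])
    lapply(split_idx, function(ix) trip[ix, , drop = FALSE])
  } else list()
  sl <- unname(sl[vapply(sl, nrow, 0L) > 0])
  if (!is.na(count_declared) && count_declared != length(sl))
    stopf("TCK count field (%d) does not match streamlines present (%d)",
          count_declared, length(sl))
  new_streamline_set(sl,
                     vapply(sl, polyline_length, 0),
                     matrix(NA_integer_, length(sl), 2),
                     rep(NA, length(sl)),
                     step_mm = NA_real_)
}

find_bytes <- function(raw, pat) {
  hits <- which(raw == pat[1])
  for (h in hits) {
    if (h + length(pat) - 1 > length(raw)) next
    if (all(raw[h:(h + length(pat) - 1)] == pat)) return(h)
  }
  NA_integer_
}

#' Write a segment label volume as NIfTI-1
#'
#' Int16 data with the voxel-to-world affine stored in the sform/qform
#' (voxel-center convention, 0-based indices).
#'
#' @param labels a `segment_label_volume`.
#' @param path output `.nii` / `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(labels, path) {
  img <- RNifti::asNifti(labels$grid, datatype = "int16")
  img <- RNifti::`sform<-`(img, structure(labels$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(labels$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a segment label volume from NIfTI-1
#'
#' @param path NIfTI file with integer labels (0 background, 1-6 V1, 7-12 V2,
#'   13 CSF).
#' @return a `segment_label_volume`.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  grid <- array(as.integer(round(as.array(img))), dim = dim(img))
  vox <- sqrt(sum(affine[1:3, 1]^2))
  structure(list(grid = grid, affine = affine, voxel_size_mm = vox,
                 csf_label = 13L),
            class = "segment_label_volume")
}

#' Write a BOLD run as TSV plus JSON sidecar
#'
#' The TSV holds one row per vertex, one column per time point; the sidecar
#' carries `tr_s`, `cycle_period_s`, `n_cycles`, `direction`, `dimension`.
#'
#' @param run a `bold_run`.
#' @param prefix output path prefix (writes `<prefix>.tsv`, `<prefix>.json`).
#' @return the prefix, invisibly.
#' @export
write_bold_run <- function(run, prefix) {
  m <- run$series
  colnames(m) <- sprintf("t%04d", seq_len(ncol(m)) - 1)
  utils::write.table(m, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- run[c("tr_s", "cycle_period_s", "n_cycles", "direction", "dimension")]
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a BOLD run written by [write_bold_run()]
#'
#' @param prefix path prefix of the TSV/JSON pair.
#' @return a `bold_run`.
#' @export
read_bold_run <- function(prefix) {
  m <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(c(list(series = m), meta), class = "bold_run")
}

#' Write a connectivity matrix as CSV with JSON sidecar
#'
#' Counts and percent matrices as CSVs with `V1_1..V1_6` row and
#' `V2_1..V2_6` column headers, plus a JSON sidecar with hemisphere,
#' acquisition and retention tallies.
#'
#' @param m a `connectivity_matrix`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_connectivity_csv <- function(m, prefix) {
  utils::write.csv(m$counts, paste0(prefix, "_counts.csv"))
  utils::write.csv(m$percent, paste0(prefix, "_percent.csv"))
  meta <- list(hemisphere_id = m$hemisphere_id, acquisition_id = m$acquisition_id,
               total = m$total, n_discarded = m$n_discarded,
               n_csf_discarded = m$n_csf_discarded,
               percent_defined = m$percent_defined,
               schema = "retinoconn-connectivity-v1")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a connectivity matrix written by [write_connectivity_csv()]
#'
#' @param prefix path prefix of the CSV/JSON triple.
#' @return a `connectivity_matrix`.
#' @export
read_connectivity_csv <- function(prefix) {
  counts <- as.matrix(utils::read.csv(paste0(prefix, "_counts.csv"), row.names = 1))
  percent <- as.matrix(utils::read.csv(paste0(prefix, "_percent.csv"), row.names = 1))
  colnames(counts) <- colnames(percent) <- v1v2_dimnames()[[2]]
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(counts = counts, percent = percent, total = meta$total,
                 percent_defined = isTRUE(meta$percent_defined),
                 n_csf_discarded = meta$n_csf_discarded,
                 n_discarded = meta$n_discarded,
                 hemisphere_id = meta$hemisphere_id,
                 acquisition_id = meta$acquisition_id),
            class = "connectivity_matrix")
}
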