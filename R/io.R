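# Coordinate and tabular readers/writers.
#
# PDB support is a deliberate fixed-width subset: ATOM/HETATM records without
# altloc or insertion codes; anything else in those columns is rejected
# loudly. Coordinates are Angstrom everywhere; XYZ comment-line times are ns.

.parse_pdb_element <- function(line, atom_name) {
  el <- trimws(substr(line, 77, 78))
  if (nzchar(el)) return(el)
  # fall back to the first alphabetic character of the atom name
  nm <- gsub("[^A-Za-z].*$", "", trimws(atom_name))
  if (!nzchar(nm)) stop("cannot infer element from atom name '", atom_name, "'")
  substr(toupper(nm), 1, 1)
}

#' Read a single-frame coordinate file
#'
#' @param path File path.
#' @param format `"pdb"`, `"xyz"` or `"auto"` (by extension).
#' @param box Box edges in Angstrom; required for XYZ unless the comment line
#'   carries `box=<x>,<y>,<z>`; for PDB taken from CRYST1 when present.
#' @param radii,default_radius Radius assignment, see [assign_radii()].
#' @return A `molecular_frame`.
#' @export
read_frame <- function(path, format = c("auto", "pdb", "xyz"), box = NULL,
                       radii = default_radii(), default_radius = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", xyz = "xyz",
                     stop("cannot recognise format of '", path,
                          "'; pass format explicitly"))
  }
  if (format == "pdb") .read_pdb(path, box, radii, default_radius)
  else .read_xyz_block(readLines(path), path, 1L, box, radii, default_radius)
}

.read_pdb <- function(path, box, radii, default_radius) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (is.null(box) && length(cr)) {
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
  }
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  parse_one <- function(k) {
    ln <- lines[k]
    if (nchar(ln) < 54)
      stop("unparseable PDB line ", k, " in ", path, " (too short)")
    altloc <- substr(ln, 17, 17)
    icode <- substr(ln, 27, 27)
    if (altloc != " ")
      stop("PDB line ", k, ": altloc codes are not supported")
    if (icode != " ")
      stop("PDB line ", k, ": insertion codes are not supported")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    resi <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (anyNA(xyz) || is.na(resi))
      stop("unparseable PDB line ", k, " in ", path)
    nm <- trimws(substr(ln, 13, 16))
    data.frame(element = .parse_pdb_element(ln, nm),
               atom_name = nm,
               residue_name = trimws(substr(ln, 18, 20)),
               residue_index = resi,
               chain_id = substr(ln, 22, 22),
               x = xyz[1], y = xyz[2], z = xyz[3])
  }
  atoms <- do.call(rbind, lapply(rec, parse_one))
  if (is.null(box)) {
    # analysis box defaulting to a loose bounding cube when none is recorded
    span <- apply(atoms[, c("x", "y", "z")], 2, function(v) diff(range(v)))
    box <- rep(max(span) + 20, 3)
  }
  molecular_frame(atoms, box, radii = radii, default_radius = default_radius)
}

# parse one XYZ block starting at line `start`; returns list(frame, next_line)
.read_xyz_block <- function(lines, path, start, box, radii, default_radius,
                            return_next = FALSE) {
  if (start > length(lines)) stop("unexpected end of file in ", path)
  n <- suppressWarnings(as.integer(trimws(lines[start])))
  if (is.na(n) || n < 1L)
    stop("format error in ", path, " line ", start,
         ": expected an atom count")
  comment <- if (start + 1L <= length(lines)) lines[start + 1L] else
    stop("unexpected end of file in ", path)
  if (start + 1L + n > length(lines))
    stop("format error in ", path, ": header declares ", n,
         " atoms but block starting at line ", start, " is short")
  body <- lines[seq(start + 2L, length.out = n)]
  if (length(body) < n || anyNA(body) || any(!nzchar(trimws(body))))
    stop("format error in ", path, ": header declares ", n,
         " atoms but block starting at line ", start, " is short")
  tm <- NA_real_
  m <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
  if (length(m) == 2L) tm <- as.numeric(m[2])
  bx <- box
  mb <- regmatches(comment,
                   regexec("box=\\s*([-0-9.eE+]+),([-0-9.eE+]+),([-0-9.eE+]+)",
                           comment))[[1]]
  if (length(mb) == 4L) bx <- as.numeric(mb[2:4])
  if (is.null(bx)) stop("no box for XYZ file ", path,
                        " (pass `box` or encode box=... in the comment line)")
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad))
    stop("unparseable line ", start + 1L + bad[1], " in ", path)
  el <- vapply(fields, `[`, character(1), 1L)
  xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric coordinates in ", path)
  # optional trailing metadata: atom_name residue_name residue_index chain_id
  meta <- function(i, default) {
    v <- vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_,
                character(1))
    ifelse(is.na(v), default, v)
  }
  atoms <- data.frame(element = el,
                      atom_name = meta(5L, el),
                      residue_name = meta(6L, "UNK"),
                      residue_index = as.integer(meta(7L, "1")),
                      chain_id = meta(8L, "A"),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  fr <- molecular_frame(atoms, bx, time = tm, radii = radii,
                        default_radius = default_radius)
  if (return_next) list(frame = fr, next_line = start + 2L + n) else fr
}

#' Read a multi-frame XYZ trajectory
#'
#' Repeated count/comment/body blocks; the comment line may carry
#' `t=<ns>` and `box=<x>,<y>,<z>`. Missing times default to the 0-based
#' frame index; all frames must have the same atom count.
#'
#' @inheritParams read_frame
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, box = NULL, radii = default_radii(),
                            default_radius = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) stop("empty trajectory file: ", path)
  frames <- list()
  at <- 1L
  while (at <= length(lines)) {
    blk <- .read_xyz_block(lines, path, at, box, radii, default_radius,
                           return_next = TRUE)
    frames[[length(frames) + 1L]] <- blk$frame
    at <- blk$next_line
  }
  n0 <- nrow(frames[[1]]$atoms)
  counts <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (any(counts != n0))
    stop("inconsistent atom count across frames in ", path, ": ",
         paste(unique(counts), collapse = " vs "))
  trajectory(frames, metadata = paste("read from", path))
}

#' Write a frame to PDB or XYZ
#'
#' @param frame A `molecular_frame`.
#' @param path Output path.
#' @param format `"pdb"`, `"xyz"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", xyz = "xyz",
                     stop("cannot recognise format of '", path, "'"))
  }
  if (format == "pdb") {
    a <- frame$atoms
    hdr <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                   frame$box[1], frame$box[2], frame$box[3])
    recs <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                    seq_len(nrow(a)) %% 100000L, substr(a$atom_name, 1, 4),
                    substr(a$residue_name, 1, 3), substr(a$chain_id, 1, 1),
                    a$residue_index %% 10000L, a$x, a$y, a$z, a$element)
    writeLines(c(hdr, recs, "END"), path)
  } else {
    writeLines(.format_xyz_block(frame), path)
  }
  invisible(path)
}

.format_xyz_block <- function(frame) {
  a <- frame$atoms
  comment <- sprintf("t=%.6f box=%.6f,%.6f,%.6f",
                     if (is.na(frame$time)) 0 else frame$time,
                     frame$box[1], frame$box[2], frame$box[3])
  c(as.character(nrow(a)), comment,
    sprintf("%-2s %12.6f %12.6f %12.6f %-4s %-4s %d %s",
            a$element, a$x, a$y, a$z, a$atom_name, a$residue_name,
            a$residue_index, a$chain_id))
}

#' Write a trajectory as multi-frame XYZ
#' @param traj A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  writeLines(unlist(lapply(traj$frames, .format_xyz_block)), path)
  invisible(path)
}

#' Read a delimited time-series table
#'
#' @param path CSV path with a header row; one time column and >= 1 signal
#'   columns.
#' @param time_col Name of the time column (default `"time"`).
#' @param sort_time If `TRUE`, unsorted times are sorted with a warning;
#'   if `FALSE` (default) they are an error.
#' @return `data.frame` of class `timeseries_table`; rows with non-numeric
#'   signal entries are kept (as NA) and flagged in attribute
#'   `flagged_rows`.
#' @export
read_timeseries <- function(path, time_col = "time", sort_time = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("empty or unreadable time-series file: ", path))
  if (!nrow(raw) || !ncol(raw)) stop("empty time-series file: ", path)
  if (!(time_col %in% names(raw)))
    stop("no '", time_col, "' column in ", path)
  if (ncol(raw) < 2L) stop("no signal columns in ", path)
  tm <- suppressWarnings(as.numeric(raw[[time_col]]))
  if (anyNA(tm)) stop("non-numeric time values in ", path)
  flagged <- integer(0)
  for (cn in setdiff(names(raw), time_col)) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    flagged <- union(flagged, which(is.na(v) & !is.na(raw[[cn]]) &
                                      nzchar(trimws(as.character(raw[[cn]])))))
    raw[[cn]] <- v
  }
  raw[[time_col]] <- tm
  if (is.unsorted(tm, strictly = TRUE)) {
    if (!sort_time) stop("time column in ", path,
                         " is not strictly increasing (set sort_time = TRUE)")
    warning("sorting time series read from ", path)
    raw <- raw[order(tm), , drop = FALSE]
    if (is.unsorted(raw[[time_col]], strictly = TRUE))
      stop("duplicate time points in ", path)
  }
  attr(raw, "flagged_rows") <- sort(flagged)
  class(raw) <- c("timeseries_table", "data.frame")
  raw
}
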