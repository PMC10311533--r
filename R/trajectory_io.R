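# Multi-frame XYZ trajectory I/O and relabelling.
#
# A trajectory is stored column-dense: one element vector shared by all
# frames plus an natoms x 3 x nframes coordinate array (Angstrom). Frame
# indices refer to positions in the source file (0-based), times are in fs.

#' Construct a trajectory object
#'
#' @param elements Character vector of element symbols (one per atom).
#' @param coords Numeric array `natoms x 3 x nframes` of Cartesian
#'   coordinates in Angstrom. A single `natoms x 3` matrix is accepted for a
#'   one-frame trajectory.
#' @param frame_index Integer vector of source frame numbers (0-based);
#'   defaults to `0:(nframes-1)`. Must be strictly increasing.
#' @param times Numeric vector of frame times in fs, or `NULL`.
#' @param source Optional source path string.
#' @param stride Stride that was applied when reading, for provenance.
#' @return An object of class `xyz_trajectory`.
#' @export
trajectory <- function(elements, coords, frame_index = NULL, times = NULL,
                       source = NA_character_, stride = 1L) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (length(elements) != dim(coords)[1])
    stop("length of `elements` (", length(elements),
         ") does not match coordinate rows (", dim(coords)[1], ")")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  nf <- dim(coords)[3]
  if (is.null(frame_index)) frame_index <- seq_len(nf) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != nf || (nf > 1L && any(diff(frame_index) <= 0L)))
    stop("frame indices must be strictly increasing, one per frame")
  if (!is.null(times) && length(times) != nf)
    stop("`times` must have one entry per frame")
  structure(
    list(elements = as.character(elements), coords = coords,
         frame_index = frame_index, times = times,
         source = source, stride = as.integer(stride)),
    class = "xyz_trajectory")
}

#' @export
print.xyz_trajectory <- function(x, ...) {
  cat("<xyz_trajectory> ", n_frames(x), " frame(s), ", n_atoms(x),
      " atoms (", paste(utils::head(unique(x$elements), 6), collapse = " "),
      if (length(unique(x$elements)) > 6) " ..." else "", ")\n", sep = "")
  if (!is.na(x$source)) cat("  source: ", x$source, " (stride ", x$stride, ")\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj An `xyz_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame from a trajectory
#'
#' @param traj An `xyz_trajectory`.
#' @param i Frame position, 1-based within the trajectory object.
#' @return List with `index` (source frame number, 0-based), `time` (fs or
#'   `NA`), `elements`, and the `natoms x 3` coordinate matrix `coords`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  list(index = traj$frame_index[i],
       time = if (is.null(traj$times)) NA_real_ else traj$times[i],
       elements = traj$elements,
       coords = traj$coords[, , i, drop = TRUE])
}

# time from an (extended-)XYZ comment line: "time = 30.0", "time_fs 30",
# "t=30.0" ... Only the time field is interpreted; other fields ignored.
.parse_comment_time <- function(line) {
  m <- regmatches(line, regexpr("\\b(time(_fs)?|t)\\s*[=: ]\\s*([0-9][0-9.eE+-]*)",
                                line, ignore.case = TRUE, perl = TRUE))
  if (length(m) == 0L) return(NA_real_)
  suppressWarnings(as.numeric(sub(".*[=: ]\\s*", "", m)))
}

#' Read a multi-frame XYZ trajectory
#'
#' Reads standard or extended XYZ (per frame: an atom-count line, a comment
#' line, then one `element x y z` line per atom) and keeps frames
#' `0, stride, 2*stride, ...` of the file. The element sequence must be
#' identical in every frame. Frame time is taken from the comment line when
#' a `time`/`t` field is present, otherwise `frame_index * dt_fs`.
#'
#' @param path Path to the XYZ file.
#' @param stride Keep every `stride`-th frame (default 30, matching the
#'   cadence at which susceptibility tensors are typically evaluated along
#'   a 1 fs-timestep trajectory).
#' @param dt_fs Assumed timestep in fs used for frame times when the file
#'   carries none.
#' @return An [trajectory()] object.
#' @export
read_xyz_trajectory <- function(path, stride = 30L, dt_fs = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("`stride` must be a positive integer")
  lines <- readLines(path)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) lines <- lines[-length(lines)]
  pos <- 1L; iframe <- 0L
  elements0 <- NULL
  coord_list <- list(); idx_list <- integer(); time_list <- numeric()
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L)
      stop("parse error at frame ", iframe, ": expected atom count, got '",
           lines[pos], "'")
    if (pos + 1L + nat > length(lines))
      stop("parse error at frame ", iframe, ": header says ", nat,
           " atoms but the file ends early")
    body <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad))
      stop("parse error at frame ", iframe, ": atom line ", bad[1],
           " has fewer than 4 fields")
    elems <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) suppressWarnings(as.numeric(tk[2:4])),
                    numeric(3)))
    if (any(!is.finite(xyz)))
      stop("parse error at frame ", iframe, ": non-numeric coordinate")
    # guard against a header that undercounts: next line would have to be a
    # bare integer (atom count) or EOF
    if (pos + 2L + nat <= length(lines)) {
      nxt <- suppressWarnings(as.integer(trimws(lines[pos + 2L + nat])))
      if (is.na(nxt))
        stop("parse error at frame ", iframe, ": header says ", nat,
             " atoms but the frame body does not end there")
    }
    if (is.null(elements0)) {
      elements0 <- elems
    } else if (!identical(elems, elements0)) {
      stop("format error at frame ", iframe,
           ": element sequence differs from frame 0")
    }
    if (iframe %% stride == 0L) {
      coord_list[[length(coord_list) + 1L]] <- xyz
      idx_list <- c(idx_list, iframe)
      tm <- .parse_comment_time(lines[pos + 1L])
      time_list <- c(time_list, if (is.na(tm)) iframe * dt_fs else tm)
    }
    pos <- pos + 2L + nat
    iframe <- iframe + 1L
  }
  if (length(coord_list) == 0L) stop("no frames found in ", path)
  coords <- array(unlist(coord_list), dim = c(nat, 3L, length(coord_list)))
  for (k in seq_along(coord_list)) coords[, , k] <- coord_list[[k]]
  trajectory(elements0, coords, frame_index = idx_list, times = time_list,
             source = path, stride = stride)
}

#' Relabel an element throughout a trajectory
#'
#' Replaces every occurrence of one element symbol with another, leaving
#' coordinates bitwise unchanged — the isostructural-substitution step
#' (e.g. replacing Gd by Dy before computing magnetic properties). The
#' number of substituted atoms is attached as attribute `n_substituted`;
#' zero occurrences raises a warning, not an error.
#'
#' @param traj An `xyz_trajectory`.
#' @param from_symbol,to_symbol Element symbols.
#' @return The relabelled trajectory.
#' @export
substitute_element <- function(traj, from_symbol, to_symbol) {
  stopifnot(inherits(traj, "xyz_trajectory"),
            is.character(from_symbol), is.character(to_symbol),
            nzchar(from_symbol), nzchar(to_symbol))
  hit <- traj$elements == from_symbol
  if (!any(hit))
    warning("no '", from_symbol, "' atoms found; trajectory unchanged")
  traj$elements[hit] <- to_symbol
  attr(traj, "n_substituted") <- sum(hit)
  traj
}

#' Write a trajectory as multi-frame XYZ
#'
#' One block per frame: atom count, a comment line `frame <i> time_fs <t>`,
#' then `element x y z` with coordinates printed to 8 decimal places.
#'
#' @param traj A non-empty `xyz_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "xyz_trajectory"))
  if (n_frames(traj) < 1L) stop("cannot write an empty trajectory")
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  nat <- n_atoms(traj)
  for (k in seq_len(n_frames(traj))) {
    tm <- if (is.null(traj$times)) traj$frame_index[k] else traj$times[k]
    writeLines(c(as.character(nat),
                 sprintf("frame %d time_fs %.4f", traj$frame_index[k], tm)),
               con)
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f", traj$elements,
                       traj$coords[, 1, k], traj$coords[, 2, k],
                       traj$coords[, 3, k]), con)
  }
  invisible(path)
}

#' Donor map: which atoms form the coordination cage
#'
#' Identifies the metal centre, the three carboxylate O donors, the three
#' macrocycle (axial) N donors, the three pyridyl (equatorial) N donors,
#' and the three pyridyl-proton triplets H1/H2/H3. All indices are
#' **0-based** to match coordinate-array conventions.
#'
#' @param metal Index of the metal atom.
#' @param o_donors,n_ax,n_eq Integer vectors of exactly 3 donor indices.
#' @param h_triplets Named list `list(H1 =, H2 =, H3 =)` of 3 indices each.
#' @param n_atoms Optional atom count for bound checking.
#' @return An object of class `donor_map`.
#' @export
donor_map <- function(metal, o_donors, n_ax, n_eq, h_triplets, n_atoms = NULL) {
  metal <- as.integer(metal)
  o_donors <- as.integer(o_donors); n_ax <- as.integer(n_ax)
  n_eq <- as.integer(n_eq)
  if (length(o_donors) != 3L || length(n_ax) != 3L || length(n_eq) != 3L)
    stop("each donor group must have exactly 3 members")
  if (!is.list(h_triplets) || !setequal(names(h_triplets), c("H1", "H2", "H3")))
    stop("`h_triplets` must be a named list with entries H1, H2, H3")
  h_triplets <- lapply(h_triplets[c("H1", "H2", "H3")], as.integer)
  if (any(lengths(h_triplets) != 3L))
    stop("each H triplet must have exactly 3 members")
  all_idx <- c(metal, o_donors, n_ax, n_eq, unlist(h_triplets))
  if (anyDuplicated(all_idx)) stop("donor-map indices must be distinct")
  if (any(all_idx < 0L)) stop("donor-map indices are 0-based and non-negative")
  if (!is.null(n_atoms) && any(all_idx >= n_atoms))
    stop("donor-map index out of range for ", n_atoms, " atoms")
  structure(list(metal = metal, o_donors = o_donors, n_ax = n_ax, n_eq = n_eq,
                 h_triplets = h_triplets),
            class = "donor_map")
}

#' @export
print.donor_map <- function(x, ...) {
  cat("<donor_map> (0-based indices)\n",
      " metal: ", x$metal, "\n",
      " O donors:  ", paste(x$o_donors, collapse = " "), "\n",
      " N_ax:      ", paste(x$n_ax, collapse = " "), "\n",
      " N_eq:      ", paste(x$n_eq, collapse = " "), "\n",
      " H triplets: ",
      paste(vapply(names(x$h_triplets),
                   function(h) paste0(h, "=[", paste(x$h_triplets[[h]], collapse = " "), "]"),
                   ""), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read / write a donor map as YAML or JSON
#'
#' File format: top-level keys `metal`, `o_donors`, `n_ax`, `n_eq`,
#' `h_triplets` (the latter a mapping H1/H2/H3 to 3 indices each), 0-based.
#' The format is chosen by file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path File path.
#' @param n_atoms Optional atom count for bound checking.
#' @return A [donor_map()].
#' @export
read_donor_map <- function(path, n_atoms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  donor_map(lst$metal, lst$o_donors, lst$n_ax, lst$n_eq,
            lapply(lst$h_triplets, as.integer), n_atoms = n_atoms)
}

#' @rdname read_donor_map
#' @param donors A [donor_map()] to write.
#' @export
write_donor_map <- function(donors, path) {
  stopifnot(inherits(donors, "donor_map"))
  lst <- unclass(donors)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

# 0-based donor-map index -> 1-based R row index
.idx1 <- function(i) i + 1L
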