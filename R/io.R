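#' Read a recording from an HDF5 container
#'
#' Reads one named struct (HDF5 group) laid out like the dataset's MAT v7.3
#' files: datasets `x` (continuous signal, samples x channels), `t` (marker
#' sample indices), `fs`, `y_dec`, `y_logic` (classes x trials), `y_class`
#' (class names) and `chan` (channel labels). Only the HDF5 layer is used, so
#' plain HDF5 files with the same group layout are accepted; pre-v7.3 binary
#' MAT dialects are not supported.
#'
#' @param path path to an HDF5 (.h5 / MAT v7.3 style) file.
#' @param struct_name name of the group holding the recording, e.g.
#'   `"EEG_MI_train"`.
#' @param code_map optional named integer vector mapping event codes to class
#'   indices when marker codes do not equal `y_dec` (e.g. artifact runs).
#' @return A list with elements `rec` (a [continuous_eeg()]) and `labels`
#'   (a [label_block()], `NULL` for unlabeled segments).
#' @export
read_recording <- function(path, struct_name, code_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  info <- tryCatch(rhdf5::h5ls(path), error = function(e) {
    stop("unreadable HDF5 container: ", path, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  in_group <- info$name[info$group == paste0("/", struct_name)]
  if (!length(in_group)) {
    stop("struct '", struct_name, "' not found in ", path, call. = FALSE)
  }
  required <- c("x", "t", "fs", "chan")
  miss <- setdiff(required, in_group)
  if (length(miss)) {
    stop("struct '", struct_name, "' is missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  g <- function(field) rhdf5::h5read(path, paste0(struct_name, "/", field))
  x <- g("x")
  t_idx <- as.integer(as.vector(g("t")))
  fs <- as.numeric(g("fs"))[1]
  chan <- as.character(as.vector(g("chan")))
  kinds <- if ("chan_kind" %in% in_group) {
    as.character(as.vector(g("chan_kind")))
  } else rep("EEG", length(chan))
  meta <- if ("meta_json" %in% in_group) {
    jsonlite::fromJSON(as.character(g("meta_json"))[1], simplifyVector = TRUE)
  } else list()

  labels <- NULL
  if (all(c("y_dec", "y_class") %in% in_group)) {
    y_dec <- as.integer(as.vector(g("y_dec")))
    y_class <- as.character(as.vector(g("y_class")))
    y_logic <- if ("y_logic" %in% in_group) {
      m <- g("y_logic")
      matrix(as.integer(m != 0), nrow = nrow(m))
    } else NULL
    if (!is.null(code_map)) y_dec <- as.integer(code_map[as.character(y_dec)])
    labels <- label_block(y_dec, y_class, y_logic)
    if (length(labels) != length(t_idx)) {
      stop("label count (", length(labels), ") does not match marker count (",
           length(t_idx), ") in struct '", struct_name, "'.", call. = FALSE)
    }
  }
  codes <- if (!is.null(labels)) labels$y_dec else rep(0L, length(t_idx))
  rec <- continuous_eeg(x, fs,
                        tibble::tibble(sample = t_idx, code = codes),
                        chan, kinds, meta)
  list(rec = rec, labels = labels)
}

#' Write a recording to an HDF5 container
#'
#' Inverse of [read_recording()]: stores the continuous signal, marker onsets
#' and labels under one group using the dataset's field names
#' (`x`, `t`, `fs`, `y_dec`, `y_logic`, `y_class`, `chan`). Several structs
#' (e.g. a train and a test phase) can share one file under different group
#' names. Writing is lossless up to double precision.
#'
#' @param rec a [continuous_eeg()].
#' @param path output file path (created or extended).
#' @param struct_name group name to write under.
#' @param labels optional [label_block()]; marker count must match.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, struct_name, labels = NULL) {
  validate_continuous_eeg(rec)
  if (!is.null(labels)) {
    validate_label_block(labels)
    if (length(labels) != nrow(rec$markers)) {
      stop("label count must equal marker count.", call. = FALSE)
    }
  }
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("unwritable path (no such directory): ", path, call. = FALSE)
  if (!file.exists(path)) rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  if (rhdf5::H5Lexists(fid, struct_name)) {
    rhdf5::h5delete(fid, struct_name)
  }
  rhdf5::h5createGroup(fid, struct_name)
  w <- function(field, value) {
    rhdf5::h5write(value, fid, paste0(struct_name, "/", field))
  }
  w("x", rec$signal)
  w("t", as.double(rec$markers$sample))
  w("fs", as.double(rec$fs))
  w("chan", rec$channel_names)
  w("chan_kind", rec$channel_kinds)
  if (length(rec$meta)) {
    w("meta_json", as.character(jsonlite::toJSON(rec$meta, auto_unbox = TRUE,
                                                 digits = NA)))
  }
  if (!is.null(labels)) {
    w("y_dec", as.integer(labels$y_dec))
    w("y_logic", labels$y_logic)
    w("y_class", labels$y_class)
  }
  invisible(path)
}
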