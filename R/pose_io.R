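#' Read a pose-track CSV
#'
#' Parses the three-header-row CSV dialect emitted by markerless
#' pose-estimation software: row 1 `scorer`, row 2 `bodyparts`, row 3
#' `coords` (repeating x / y / likelihood triplets), then one data row per
#' frame with the 0-based frame index in the first column. Empty or
#' non-numeric coordinate cells become missing cells (likelihood forced to
#' 0); their count is available in the `parse_report` attribute.
#'
#' @param path path to the CSV file.
#' @param frame_rate frames per second to attach (default 50).
#' @param trial_id trial identifier; defaults to the file name without
#'   extension.
#' @return a [pose_track]. The attribute `parse_report` is a data.frame
#'   with one row per label giving the number of malformed cells repaired.
#' @export
read_pose_csv <- function(path, frame_rate = 50, trial_id = NULL) {
  if (!file.exists(path)) stop("read_pose_csv: no such file: ", path)
  if (is.null(trial_id)) trial_id <- sub("\\.[^.]*$", "", basename(path))
  head3 <- readLines(path, n = 3L)
  if (length(head3) < 3L)
    stop("read_pose_csv: '", path, "' lacks the three header rows (scorer, bodyparts, coords)")
  h <- lapply(head3, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  keys <- tolower(vapply(h, `[`, "", 1L))
  if (!identical(keys, c("scorer", "bodyparts", "coords")))
    stop("read_pose_csv: header rows must be 'scorer', 'bodyparts', 'coords'; got: ",
         paste(keys, collapse = ", "))
  parts_row <- h[[2]][-1]
  coords_row <- h[[3]][-1]
  ncol_data <- length(parts_row)
  if (length(coords_row) != ncol_data)
    stop("read_pose_csv: bodyparts and coords header rows differ in length")
  if (ncol_data %% 3 != 0)
    stop("read_pose_csv: columns do not form (x, y, likelihood) triplets")
  labels <- parts_row[seq(1, ncol_data, by = 3)]
  for (j in seq_along(labels)) {
    trip <- parts_row[(3 * j - 2):(3 * j)]
    if (!all(trip == labels[j]) ||
        !identical(tolower(coords_row[(3 * j - 2):(3 * j)]), c("x", "y", "likelihood")))
      stop("read_pose_csv: inconsistent (x, y, likelihood) triplet for label '",
           labels[j], "'")
  }
  raw <- utils::read.csv(path, skip = 3L, header = FALSE,
                         colClasses = "character",
                         col.names = c("frame", paste0("V", seq_len(ncol_data))),
                         blank.lines.skip = FALSE)
  nfr <- nrow(raw)
  to_num <- function(v) suppressWarnings(as.numeric(v))
  malformed <- integer(length(labels)); names(malformed) <- labels
  x <- y <- lik <- matrix(NA_real_, nfr, length(labels),
                          dimnames = list(NULL, labels))
  for (j in seq_along(labels)) {
    cx <- raw[[3 * j - 1]]; cy <- raw[[3 * j]]; cl <- raw[[3 * j + 1]]
    nx <- to_num(cx); ny <- to_num(cy); nl <- to_num(cl)
    # a malformed cell = non-empty text that failed numeric conversion
    bad <- (is.na(nx) & nzchar(trimws(cx))) | (is.na(ny) & nzchar(trimws(cy))) |
      (is.na(nl) & nzchar(trimws(cl)))
    malformed[j] <- sum(bad)
    nx[bad] <- NA_real_; ny[bad] <- NA_real_; nl[bad] <- NA_real_
    out <- nl[!is.na(nl)]
    if (any(out < 0 | out > 1)) {
      fr <- which(!is.na(nl) & (nl < 0 | nl > 1))[1]
      stop(sprintf("read_pose_csv: likelihood %g outside [0,1] for label '%s' at frame %d",
                   nl[fr], labels[j], fr - 1L))
    }
    miss <- is.na(nx) | is.na(ny)
    nx[miss] <- NA_real_; ny[miss] <- NA_real_
    nl[miss] <- 0; nl[is.na(nl)] <- 0
    x[, j] <- nx; y[, j] <- ny; lik[, j] <- nl
  }
  tr <- pose_track(trial_id, x, y, lik, frame_rate = frame_rate)
  attr(tr, "parse_report") <- data.frame(label = labels,
                                         malformed_cells = unname(malformed),
                                         row.names = NULL)
  tr
}

#' Write a pose-track CSV
#'
#' Emits the same three-header-row dialect read by [read_pose_csv].
#' Missing cells are written as empty x and y fields with likelihood 0, so
#' a write/read round trip reproduces the track field-for-field.
#' Coordinates are printed with 17 significant digits, which round-trips
#' IEEE doubles exactly and keeps output bytes stable across runs.
#'
#' @param track a [pose_track].
#' @param path output file path.
#' @param scorer value for the scorer header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path, scorer = "embryokin") {
  validate_pose_track(track)
  labels <- part_labels(track)
  fmt <- function(m) {
    s <- sprintf("%.17g", m)
    s[is.na(as.vector(m))] <- ""
    matrix(s, nrow = nrow(m))
  }
  nfr <- n_frames(track)
  body <- character()
  if (nfr > 0) {
    xs <- fmt(track$x); ys <- fmt(track$y)
    ls <- matrix(sprintf("%.17g", track$likelihood), nrow = nfr)
    cols <- vector("list", 3 * length(labels))
    for (j in seq_along(labels)) {
      cols[[3 * j - 2]] <- xs[, j]; cols[[3 * j - 1]] <- ys[, j]; cols[[3 * j]] <- ls[, j]
    }
    body <- do.call(paste, c(list(0:(nfr - 1)), cols, sep = ","))
  }
  lines <- c(
    paste(c("scorer", rep(scorer, 3 * length(labels))), collapse = ","),
    paste(c("bodyparts", rep(labels, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), length(labels))), collapse = ","),
    body)
  writeLines(lines, path)
  invisible(path)
}

#' Trial design
#'
#' Describes one recorded trial: the embryo, its embryonic day (ED), an
#' optional treatment-group tag, and the stimulus timeline. Exactly one
#' noxious Pinch and one control Touch are applied, in either order; each
#' has an onset frame (clamp contact) and a release frame (clamp off, the
#' start of the post-stimulus analysis window). Baseline lasts 2 min for
#' ED15-18 and 3 min for ED9-14. Frames are 0-based.
#'
#' @param embryo_id character scalar.
#' @param embryonic_day integer, one of 9 or 12..18.
#' @param stimuli data.frame with columns `kind` ("Pinch"/"Touch"),
#'   `onset_frame`, `release_frame`; one row per stimulus.
#' @param group treatment-group tag, e.g. "plain" or "w_lido".
#' @param baseline_duration baseline length in seconds; default 120 for
#'   ED15-18, 180 for ED9-14.
#' @param post_duration analyzed post-stimulus length in seconds (120).
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(embryo_id, embryonic_day, stimuli, group = "plain",
                         baseline_duration = NULL, post_duration = 120) {
  embryonic_day <- as.integer(embryonic_day)
  if (!(embryonic_day %in% c(9L, 12:18)))
    stop("trial_design: embryonic_day must be 9 or 12..18")
  if (is.null(baseline_duration))
    baseline_duration <- if (embryonic_day >= 15) 120 else 180
  stimuli <- as.data.frame(stimuli)
  need <- c("kind", "onset_frame", "release_frame")
  if (!all(need %in% names(stimuli)))
    stop("trial_design: stimuli needs columns kind, onset_frame, release_frame")
  if (!setequal(stimuli$kind, c("Pinch", "Touch")) || nrow(stimuli) != 2)
    stop("trial_design: exactly one Pinch and one Touch stimulus are required")
  if (any(stimuli$release_frame < stimuli$onset_frame))
    stop("trial_design: release_frame must be >= onset_frame")
  stimuli <- stimuli[order(stimuli$onset_frame), , drop = FALSE]
  rownames(stimuli) <- NULL
  structure(
    list(embryo_id = as.character(embryo_id),
         embryonic_day = embryonic_day,
         group = as.character(group),
         stimuli = stimuli,
         baseline_duration = baseline_duration,
         post_duration = post_duration),
    class = "trial_design")
}

#' @method print trial_design
#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("<trial_design embryo '%s', ED%d, group '%s'>\n",
              x$embryo_id, x$embryonic_day, x$group))
  cat(sprintf("  baseline %g s, analyzed post window %g s\n",
              x$baseline_duration, x$post_duration))
  for (i in seq_len(nrow(x$stimuli)))
    cat(sprintf("  %s: onset frame %d, release frame %d\n",
                x$stimuli$kind[i], x$stimuli$onset_frame[i],
                x$stimuli$release_frame[i]))
  invisible(x)
}

#' Read / write trial designs (YAML)
#'
#' A cohort design file is a YAML list with one entry per trial; each
#' entry carries embryo_id, embryonic_day, group, baseline_duration,
#' post_duration and a `stimuli` list of \{kind, onset_frame,
#' release_frame\} records.
#'
#' @param path file path.
#' @return `read_trial_designs`: a named list of [trial_design] objects.
#' @export
read_trial_designs <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(r) {
    st <- do.call(rbind, lapply(r$stimuli, function(s)
      data.frame(kind = s$kind, onset_frame = s$onset_frame,
                 release_frame = s$release_frame)))
    trial_design(r$embryo_id, r$embryonic_day, st, group = r$group %||% "plain",
                 baseline_duration = r$baseline_duration,
                 post_duration = r$post_duration %||% 120)
  })
  names(out) <- vapply(out, function(d) d$embryo_id, "")
  out
}

#' @param designs list of [trial_design] objects.
#' @rdname read_trial_designs
#' @export
write_trial_designs <- function(designs, path) {
  raw <- lapply(designs, function(d) {
    list(embryo_id = d$embryo_id, embryonic_day = d$embryonic_day,
         group = d$group, baseline_duration = d$baseline_duration,
         post_duration = d$post_duration,
         stimuli = lapply(seq_len(nrow(d$stimuli)), function(i)
           list(kind = d$stimuli$kind[i],
                onset_frame = as.integer(d$stimuli$onset_frame[i]),
                release_frame = as.integer(d$stimuli$release_frame[i]))))
  })
  yaml::write_yaml(unname(raw), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
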