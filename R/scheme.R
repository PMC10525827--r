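#' Body-part scheme
#'
#' Maps raw tracking labels onto the analysis roles: the two beak
#' boundary points whose gap is the beak-distance parameter, the beak
#' fulcrum (angle vertex), the medial eye corner (head movement), the
#' elbow and the leg (metatarsus for ED12-18; the tarsus is substituted
#' on ED9 because the ED9 metatarsus is translucent and tracks poorly),
#' plus at least one stationary reference landmark on the egg or holder
#' used as a negative control for movement.
#'
#' @param beak_upper,beak_lower,beak_fulcrum raw labels for the beak
#'   roles (required, pairwise distinct).
#' @param eye_corner,elbow,leg optional raw labels.
#' @param reference_points character vector of stationary-landmark labels.
#' @param leg_site which anatomical site the `leg` label tracks:
#'   "metatarsus" or "tarsus".
#' @return an object of class `bodypart_scheme`.
#' @export
bodypart_scheme <- function(beak_upper, beak_lower, beak_fulcrum,
                            eye_corner = NULL, elbow = NULL, leg = NULL,
                            reference_points = character(),
                            leg_site = c("metatarsus", "tarsus")) {
  leg_site <- match.arg(leg_site)
  beak <- c(beak_upper = beak_upper, beak_lower = beak_lower,
            beak_fulcrum = beak_fulcrum)
  if (anyDuplicated(beak))
    stop("bodypart_scheme: beak_upper, beak_lower and beak_fulcrum must map to distinct labels")
  roles <- c(as.list(beak),
             list(eye_corner = eye_corner, elbow = elbow, leg = leg))
  roles <- roles[!vapply(roles, is.null, TRUE)]
  structure(list(roles = roles,
                 reference_points = as.character(reference_points),
                 leg_site = leg_site),
            class = "bodypart_scheme")
}

#' @method print bodypart_scheme
#' @export
print.bodypart_scheme <- function(x, ...) {
  cat("<bodypart_scheme>\n")
  for (r in names(x$roles))
    cat(sprintf("  %-12s -> '%s'\n", r, x$roles[[r]]))
  if (!is.null(x$roles$leg)) cat("  leg site:    ", x$leg_site, "\n")
  if (length(x$reference_points))
    cat("  reference:    ", paste(x$reference_points, collapse = ", "), "\n")
  invisible(x)
}

#' Bind a body-part scheme to a pose track
#'
#' Resolves the scheme's role -> label map against the track, checking
#' that every mapped label exists and, when an embryonic day is supplied,
#' that an ED9 trial uses the tarsus as the leg landmark.
#'
#' @param track a [pose_track].
#' @param scheme a [bodypart_scheme].
#' @param embryonic_day optional ED used to enforce the ED9 tarsus rule;
#'   a [trial_design] may be passed instead.
#' @return an object of class `bound_track` giving role-based access to
#'   the underlying series via [role_xy].
#' @export
bind_scheme <- function(track, scheme, embryonic_day = NULL) {
  stopifnot(inherits(track, "pose_track"), inherits(scheme, "bodypart_scheme"))
  if (inherits(embryonic_day, "trial_design"))
    embryonic_day <- embryonic_day$embryonic_day
  all_lab <- c(unlist(scheme$roles, use.names = FALSE), scheme$reference_points)
  absent <- setdiff(all_lab, part_labels(track))
  if (length(absent))
    stop("bind_scheme: labels not present in track '", track$trial_id, "': ",
         paste(absent, collapse = ", "))
  if (!is.null(embryonic_day) && embryonic_day == 9 &&
      !is.null(scheme$roles$leg) && scheme$leg_site != "tarsus")
    stop("bind_scheme: ED9 trials must use the tarsus (not the metatarsus) as the leg landmark")
  structure(list(track = track, scheme = scheme), class = "bound_track")
}

#' Role-resolved coordinate series
#'
#' @param view a `bound_track` from [bind_scheme].
#' @param role one of the scheme's roles ("beak_upper", "beak_lower",
#'   "beak_fulcrum", "eye_corner", "elbow", "leg") or the label of a
#'   reference point.
#' @return list with numeric vectors `x` and `y` (NA where missing).
#' @export
role_xy <- function(view, role) {
  stopifnot(inherits(view, "bound_track"))
  label <- view$scheme$roles[[role]]
  if (is.null(label)) {
    if (role %in% view$scheme$reference_points) label <- role
    else stop("role_xy: role '", role, "' is not bound in this scheme")
  }
  list(x = view$track$x[, label], y = view$track$y[, label])
}

#' @method print bound_track
#' @export
print.bound_track <- function(x, ...) {
  cat(sprintf("<bound_track '%s'>\n", x$track$trial_id))
  print(x$scheme)
  invisible(x)
}
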