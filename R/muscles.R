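#' Default specification of the four wrist prime movers
#'
#' Returns the packaged table describing the four wrist prime movers used
#' throughout the package: extensor carpi radialis (ECR), extensor carpi
#' ulnaris (ECU), flexor carpi ulnaris (FCU) and flexor carpi radialis (FCR).
#' For each muscle it gives the preferred direction in cursor-space degrees
#' (right = 0, up = 90; extension moves the cursor right, radial deviation
#' up) and the admissible sign of its tension-to-torque weight on each axis.
#' The signs encode pulling directions: extensors act positively and flexors
#' negatively on the flexion/extension (x) axis; radial muscles act
#' positively and ulnar muscles negatively on the deviation (y) axis.
#'
#' The table is shipped as a YAML file under `extdata/muscle_spec.yaml` and
#' can be overridden by supplying a file of the same layout.
#'
#' @param path Optional path to a YAML file overriding the packaged default.
#' @return A data.frame with columns `name`, `pd_deg`, `sign_x`, `sign_y`.
#' @examples
#' default_muscle_spec()
#' @export
default_muscle_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "muscle_spec.yaml", package = "wristdecon")
  }
  raw <- yaml::read_yaml(path)
  spec <- do.call(rbind, lapply(raw$muscles, function(m) {
    data.frame(name = m$name, pd_deg = as.numeric(m$pd_deg),
               sign_x = as.integer(m$sign_x), sign_y = as.integer(m$sign_y),
               stringsAsFactors = FALSE)
  }))
  validate_muscle_spec(spec)
  spec
}

#' Validate a muscle specification table
#'
#' Checks the invariants a muscle table must satisfy: four distinct muscle
#' names, preferred directions covering all four quadrants of cursor space,
#' and per-axis signs in {-1, 0, +1}.
#'
#' @param spec A data.frame as returned by [default_muscle_spec()].
#' @return The validated spec, invisibly.
#' @export
validate_muscle_spec <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("name", "pd_deg", "sign_x", "sign_y") %in% names(spec)))
  if (nrow(spec) != 4L || anyDuplicated(spec$name))
    stop("muscle spec must list four distinct muscles")
  if (!all(spec$sign_x %in% c(-1L, 0L, 1L)) ||
      !all(spec$sign_y %in% c(-1L, 0L, 1L)))
    stop("muscle spec signs must be -1, 0 or +1")
  # pulling directions must positively span the torque plane: one muscle
  # per sign-pattern quadrant
  q <- paste(spec$sign_x, spec$sign_y)
  if (length(unique(q[spec$sign_x != 0 & spec$sign_y != 0])) < 4L)
    stop("pulling directions must span all four quadrants")
  invisible(spec)
}

# signed angular difference a - b wrapped to (-180, 180]
circular_difference <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
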