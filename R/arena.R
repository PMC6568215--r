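# Geometric model of the clockmaze (and watermaze variant): hole positions,
# analysis zones (holes, decoys, exit, periphery band, quadrants, platform,
# probe target/non-target zones) and point-in-zone queries.
#
# Coordinate frame: origin at the arena center, +x toward 3 o'clock, +y toward
# 12 o'clock, units cm. Angles in degrees, counterclockwise-positive.

#' Arena configuration
#'
#' Describes the circular maze geometry. The default clockmaze is an 85 cm
#' diameter shallow pool whose perimeter wall is pierced by 12 holes (4 cm
#' diameter) arranged equidistantly like the hours of a clock face; the
#' watermaze variant is a 160 cm pool with a hidden platform and no holes.
#'
#' @param variant `"clockmaze"` or `"watermaze"`.
#' @param radius_cm Arena radius in cm (default 42.5 for clockmaze, 80 for
#'   watermaze).
#' @param n_holes Number of peripheral holes (12 for clockmaze, 0 for
#'   watermaze).
#' @param hole_diameter_cm Physical hole diameter, cm (metadata).
#' @param hole_zone_radius_cm Radius of the circular error/entry zone centered
#'   on each hole, cm. Inspections of decoys are scored inside this zone.
#' @param probe_zone_radius_cm Radius of the larger probe-test target zones, cm.
#' @param periphery_band_cm Width of the thigmotaxis annulus measured inward
#'   from the wall, cm.
#' @param platform_center Numeric length-2 point (x, y) in cm, watermaze only.
#' @param platform_radius_cm Platform zone radius, cm (watermaze only).
#' @param quadrant_offset_deg Angle of the first quadrant boundary. The default
#'   45 puts each clockmaze quadrant boundary between holes so every quadrant
#'   holds exactly 3 holes; use 0 for axis-aligned quadrants.
#' @return An object of class `cm_arena_config`.
#' @export
arena_config <- function(variant = c("clockmaze", "watermaze"),
                         radius_cm = NULL,
                         n_holes = NULL,
                         hole_diameter_cm = 4.0,
                         hole_zone_radius_cm = 2.0,
                         probe_zone_radius_cm = 6.0,
                         periphery_band_cm = 8.0,
                         platform_center = NULL,
                         platform_radius_cm = 8.0,
                         quadrant_offset_deg = 45) {
  variant <- match.arg(variant)
  if (is.null(radius_cm)) {
    radius_cm <- if (variant == "clockmaze") 42.5 else 80.0
  }
  if (is.null(n_holes)) {
    n_holes <- if (variant == "clockmaze") 12L else 0L
  }
  cfg <- structure(
    list(variant = variant,
         radius_cm = as.numeric(radius_cm),
         n_holes = as.integer(n_holes),
         hole_diameter_cm = as.numeric(hole_diameter_cm),
         hole_zone_radius_cm = as.numeric(hole_zone_radius_cm),
         probe_zone_radius_cm = as.numeric(probe_zone_radius_cm),
         periphery_band_cm = as.numeric(periphery_band_cm),
         platform_center = if (is.null(platform_center)) NULL
                           else as.numeric(platform_center),
         platform_radius_cm = as.numeric(platform_radius_cm),
         quadrant_offset_deg = as.numeric(quadrant_offset_deg)),
    class = "cm_arena_config")
  validate_arena_config(cfg)
  cfg
}

validate_arena_config <- function(cfg) {
  if (!is.finite(cfg$radius_cm) || cfg$radius_cm <= 0)
    stop_config("radius_cm must be a positive length, got %s", cfg$radius_cm)
  for (fld in c("hole_zone_radius_cm", "probe_zone_radius_cm",
                "periphery_band_cm", "platform_radius_cm")) {
    v <- cfg[[fld]]
    if (!is.finite(v) || v <= 0 || v >= cfg$radius_cm)
      stop_config("%s must lie in (0, radius_cm); got %s", fld, v)
  }
  if (cfg$n_holes < 0)
    stop_config("n_holes must be >= 0, got %d", cfg$n_holes)
  if (cfg$variant == "clockmaze" && cfg$n_holes < 2)
    stop_config("clockmaze requires n_holes >= 2, got %d", cfg$n_holes)
  if (cfg$variant == "watermaze") {
    pc <- cfg$platform_center
    if (is.null(pc) || length(pc) != 2 || !all(is.finite(pc)))
      stop_config("watermaze requires a finite platform_center (x, y)")
    if (sqrt(sum(pc^2)) >= cfg$radius_cm)
      stop_config("platform_center must lie inside the arena (|c| < radius_cm)")
  }
  invisible(cfg)
}

#' Read an arena configuration from a flat JSON or YAML-style file
#'
#' Accepts either a JSON object or a flat `key: value` file; field names are
#' exactly the [arena_config()] argument names. `platform_center` may be given
#' as a two-element array (JSON) or as `"x,y"` (flat file).
#'
#' @param path File path.
#' @return A `cm_arena_config`.
#' @export
read_arena_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  body <- paste(txt, collapse = "\n")
  vals <- if (grepl("^\\s*\\{", body)) {
    jsonlite::fromJSON(body, simplifyVector = TRUE)
  } else {
    parse_flat_yaml(txt)
  }
  known <- names(formals(arena_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_config("unknown arena config field(s): %s", paste(bad, collapse = ", "))
  if (!is.null(vals$platform_center) && is.character(vals$platform_center))
    vals$platform_center <- as.numeric(strsplit(vals$platform_center, ",")[[1]])
  do.call(arena_config, vals)
}

# Minimal flat "key: value" reader (comments with '#', blank lines ignored).
parse_flat_yaml <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop_format("cannot parse config line: %s", ln)
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else gsub('^"|"$', "", val)
  }
  out
}

#' Build the arena model
#'
#' Places the hole centers on the wall circle and constructs all analysis
#' zones: one entry zone per hole, the periphery (thigmotaxis) annulus, four
#' quadrant sectors, and — for the watermaze — the platform zone.
#'
#' @param config A [arena_config()] object (default clockmaze).
#' @return An object of class `cm_arena` with elements `config`,
#'   `hole_centers` (n_holes x 2 matrix) and `zones` (named list of `cm_zone`).
#' @export
build_arena <- function(config = arena_config()) {
  validate_arena_config(config)
  R <- config$radius_cm
  centers <- hole_centers_for(config)
  zones <- list()
  if (config$n_holes > 0) {
    for (k in seq_len(config$n_holes)) {
      zones[[sprintf("hole_%02d", k)]] <-
        zone_circle(sprintf("hole_%02d", k), "hole",
                    centers[k, ], config$hole_zone_radius_cm)
    }
  }
  zones$periphery <- zone_annulus("periphery", "periphery",
                                  inner = R - config$periphery_band_cm,
                                  outer = R)
  qnames <- c("quadrant_NE", "quadrant_NW", "quadrant_SW", "quadrant_SE")
  off <- config$quadrant_offset_deg
  starts <- off + c(0, 90, 180, 270)
  for (i in seq_along(qnames)) {
    zones[[qnames[i]]] <- zone_sector(qnames[i], "quadrant",
                                      starts[i], starts[i] + 90, R)
  }
  if (config$variant == "watermaze") {
    zones$platform <- zone_circle("platform", "platform",
                                  config$platform_center,
                                  config$platform_radius_cm)
  }
  structure(list(config = config, hole_centers = centers, zones = zones),
            class = "cm_arena")
}

hole_centers_for <- function(config) {
  n <- config$n_holes
  if (n == 0L) return(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("x", "y"))))
  k <- seq_len(n)
  theta <- deg2rad(90 - (360 / n) * k)  # hole n at 12 o'clock, clockwise
  cbind(x = config$radius_cm * cos(theta),
        y = config$radius_cm * sin(theta))
}

#' Hole center coordinates in clock order
#'
#' Hole `k` sits at the clock position `k`: hole 12 at the top (0, R), hole 3
#' at (R, 0), numbering clockwise, all centers exactly on the wall circle.
#'
#' @param arena A clockmaze `cm_arena`.
#' @return n_holes x 2 matrix of (x, y) cm, row `k` = hole `k`.
#' @export
hole_positions <- function(arena) {
  stopifnot(inherits(arena, "cm_arena"))
  if (arena$config$variant != "clockmaze")
    stop_capability("hole_positions is only defined for the clockmaze variant")
  arena$hole_centers
}

# ---- zones ------------------------------------------------------------------

zone_circle <- function(name, kind, center, radius) {
  structure(list(name = name, kind = kind, geom = "circle",
                 center = as.numeric(center), radius = as.numeric(radius)),
            class = "cm_zone")
}

zone_annulus <- function(name, kind, inner, outer) {
  structure(list(name = name, kind = kind, geom = "annulus",
                 inner = as.numeric(inner), outer = as.numeric(outer)),
            class = "cm_zone")
}

# Sector spanning [a0, a1] degrees CCW from a0 to a1, full radius.
zone_sector <- function(name, kind, a0, a1, radius) {
  structure(list(name = name, kind = kind, geom = "sector",
                 a0 = as.numeric(a0), a1 = as.numeric(a1),
                 radius = as.numeric(radius)),
            class = "cm_zone")
}

#' Test whether points lie inside a zone
#'
#' Zones are closed sets: boundary points belong to the zone.
#'
#' @param p Numeric length-2 point or an n x 2 matrix of points (cm).
#' @param zone A `cm_zone`.
#' @return Logical vector, one element per point.
#' @export
point_in_zone <- function(p, zone) {
  stopifnot(inherits(zone, "cm_zone"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  switch(zone$geom,
    circle = {
      d2 <- (p[, 1] - zone$center[1])^2 + (p[, 2] - zone$center[2])^2
      d2 <= zone$radius^2 + 1e-12
    },
    annulus = {
      r <- row_norm(p)
      r >= zone$inner - 1e-9 & r <= zone$outer + 1e-9
    },
    sector = {
      r <- row_norm(p)
      ang <- (rad2deg(atan2(p[, 2], p[, 1])) - zone$a0) %% 360
      span <- (zone$a1 - zone$a0) %% 360
      if (span == 0) span <- 360
      inside <- r <= zone$radius + 1e-9 &
        (ang <= span + 1e-9 | ang >= 360 - 1e-9)
      # the arena center belongs to every sector (boundary point)
      inside | r < 1e-12
    },
    stop_validation("unknown zone geometry: %s", zone$geom))
}

#' Decoy zones for a given true exit
#'
#' @param arena A clockmaze `cm_arena`.
#' @param true_exit Hole index of the open exit (1..n_holes).
#' @return Named list of the `n_holes - 1` hole zones excluding the true exit.
#' @export
decoy_zones <- function(arena, true_exit) {
  stopifnot(inherits(arena, "cm_arena"))
  n <- arena$config$n_holes
  if (!is.numeric(true_exit) || length(true_exit) != 1 ||
      true_exit < 1 || true_exit > n)
    stop_validation("true_exit must be a hole index in 1..%d", n)
  holes <- arena$zones[grepl("^hole_", names(arena$zones))]
  holes[-as.integer(true_exit)]
}

#' Probe-test target/non-target zones
#'
#' Larger circular zones (radius `probe_zone_radius_cm`) centered on every
#' hole; the zone at `former_exit` is the target zone (TZ), the rest are the
#' non-target zones (NT).
#'
#' @param arena A clockmaze `cm_arena`.
#' @param former_exit Hole index of the formerly open exit.
#' @return List with elements `target` (one `cm_zone`) and `nontarget` (list).
#' @export
probe_zones <- function(arena, former_exit) {
  stopifnot(inherits(arena, "cm_arena"))
  n <- arena$config$n_holes
  if (missing(former_exit) || !is.numeric(former_exit) ||
      length(former_exit) != 1 || former_exit < 1 || former_exit > n)
    stop_validation("former_exit must be a hole index in 1..%d", n)
  r <- arena$config$probe_zone_radius_cm
  zs <- lapply(seq_len(n), function(k) {
    kind <- if (k == former_exit) "target" else "nontarget"
    zone_circle(sprintf("probe_%02d", k), kind, arena$hole_centers[k, ], r)
  })
  list(target = zs[[as.integer(former_exit)]],
       nontarget = zs[-as.integer(former_exit)])
}

#' @export
print.cm_arena <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cm_arena %s: R = %.1f cm, %d holes, %d zones>\n",
              cfg$variant, cfg$radius_cm, cfg$n_holes, length(x$zones)))
  invisible(x)
}
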