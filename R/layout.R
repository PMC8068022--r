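#' Sensor layout: 18 sensing regions over 361 sensels
#'
#' The pressure glove exposes 361 sensing elements ("sensels") grouped into 18
#' anatomical regions (distal/intermediate/proximal phalanges of thumb and
#' fingers, distal palm, thenar and hypothenar eminences). A `sensor_layout`
#' holds the region map, geometry constants (4 mm pitch, 16 mm^2 sensel area,
#' 517 kPa full scale) and schematic render coordinates used by the signature
#' plots.
#'
#' @param path Path to a layout JSON file. See [default_layout()] for the
#'   packaged one.
#' @return An object of class `sensor_layout`: a list with elements
#'   `regions` (data.frame: id, label, class, sensel_count, x, y),
#'   `sensel_ids` (list of integer vectors, one per region),
#'   `region_of_sensel` (integer vector of length `n_sensels`),
#'   and constants `pitch_mm`, `sensel_area_mm2`, `pressure_max_kpa`,
#'   `n_sensels`.
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed layout JSON: ",
                                           conditionMessage(e)))
  req <- c("pitch_mm", "sensel_area_mm2", "pressure_max_kPa",
           "n_sensels_total", "regions")
  missing <- setdiff(req, names(doc))
  if (length(missing))
    stop("malformed layout: missing field(s) ", paste(missing, collapse = ", "))

  regs <- doc$regions
  get_num <- function(r, f) {
    if (is.null(r[[f]])) stop("malformed layout: region missing field '", f, "'")
    r[[f]]
  }
  ids <- vapply(regs, get_num, numeric(1), f = "id")
  labels <- vapply(regs, get_num, character(1), f = "label")
  classes <- vapply(regs, get_num, character(1), f = "class")
  sensel_ids <- lapply(regs, function(r)
    as.integer(unlist(get_num(r, "sensel_ids"))))
  xy <- t(vapply(regs, function(r) as.numeric(unlist(get_num(r, "render_xy"))),
                 numeric(2)))

  layout <- structure(list(
    regions = data.frame(
      id = as.integer(ids), label = labels, class = classes,
      sensel_count = lengths(sensel_ids), x = xy[, 1], y = xy[, 2],
      stringsAsFactors = FALSE),
    sensel_ids = sensel_ids,
    region_of_sensel = NULL,
    pitch_mm = as.numeric(doc$pitch_mm),
    sensel_area_mm2 = as.numeric(doc$sensel_area_mm2),
    pressure_max_kpa = as.numeric(doc$pressure_max_kPa),
    n_sensels = as.integer(doc$n_sensels_total)
  ), class = "sensor_layout")

  ros <- integer(layout$n_sensels)
  for (i in seq_along(sensel_ids)) ros[sensel_ids[[i]]] <- i
  layout$region_of_sensel <- ros
  validate_layout(layout)
  layout
}

#' @rdname load_layout
#' @export
default_layout <- function() {
  load_layout(system.file("extdata", "grip_layout.json", package = "gripsig",
                          mustWork = TRUE))
}

#' Validate a sensor layout against its structural invariants
#'
#' Checks that region ids are exactly 1..18, the sensel ids partition
#' 1..n_sensels with no overlap, per-region counts sum to the total, the
#' sensel area equals the squared pitch, and region classes are valid.
#'
#' @param layout A `sensor_layout`.
#' @return The layout, invisibly; stops with a message naming the violated
#'   invariant otherwise.
#' @export
validate_layout <- function(layout) {
  r <- layout$regions
  if (!identical(sort(r$id), 1:18))
    stop("layout invariant violated: region ids must be exactly 1..18")
  if (!all(r$class %in% c("thumb", "finger", "palm")))
    stop("layout invariant violated: region class must be thumb/finger/palm")
  if (sum(r$sensel_count) != layout$n_sensels)
    stop("layout invariant violated: region sensel counts sum to ",
         sum(r$sensel_count), ", expected ", layout$n_sensels)
  all_ids <- sort(unlist(layout$sensel_ids))
  if (!identical(all_ids, seq_len(layout$n_sensels)))
    stop("layout invariant violated: sensel ids must partition 1..",
         layout$n_sensels, " with no overlap")
  if (abs(layout$sensel_area_mm2 - layout$pitch_mm^2) > 1e-9)
    stop("layout invariant violated: sensel_area_mm2 must equal pitch_mm^2")
  invisible(layout)
}

#' Region class helpers
#'
#' Regions 1-2 are thumb, 3-14 finger phalanges, 15-18 palm areas (including
#' the thenar and hypothenar eminences). Used by the opposition-graph rule.
#'
#' @param layout A `sensor_layout`.
#' @return Character vector of length 18 with values thumb/finger/palm.
#' @export
region_classes <- function(layout) {
  layout$regions$class[order(layout$regions$id)]
}

#' Convert pressure from psi to kPa
#'
#' The sensor's calibrated map spans 0-75 psi, i.e. 0-517 kPa; conversions use
#' that full-scale equivalence.
#'
#' @param psi Pressure in psi.
#' @return Pressure in kPa.
#' @export
psi_to_kpa <- function(psi) psi * (517 / 75)

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %d regions, %d sensels, pitch %g mm, %g kPa max\n",
              nrow(x$regions), x$n_sensels, x$pitch_mm, x$pressure_max_kpa))
  invisible(x)
}
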