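#' Write enumeration areas as GeoJSON
#'
#' One Feature per EA with its outline polygon and attribute
#' properties. Coordinates are planar metres (no geographic CRS): the
#' synthetic world lives in a local projected frame.
#'
#' @param eas an [ea_set()].
#' @param file output path.
#' @export
write_ea_geojson <- function(eas, file) {
  stopifnot(inherits(eas, "ea_set"))
  tab <- eas$table
  features <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$ea_id[i]
    ring <- eas$polygons[[id]]
    props <- as.list(tab[i, setdiff(names(tab), character(0)), drop = FALSE])
    list(
      type = "Feature",
      geometry = if (is.null(ring)) NULL else list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(j) unname(ring[j, ])))
      ),
      properties = props
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(file)
}

#' Read enumeration areas from GeoJSON
#'
#' @param file path written by [write_ea_geojson()] or conforming
#'   GeoJSON with the same properties.
#' @return An [ea_set()] (without pixel membership).
#' @export
read_ea_geojson <- function(file) {
  fc <- jsonlite::read_json(file)
  if (!identical(fc$type, "FeatureCollection")) stop("not a FeatureCollection")
  rows <- lapply(fc$features, function(f) {
    as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  polys <- lapply(fc$features, function(f) {
    if (is.null(f$geometry)) return(NULL)
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
    colnames(m) <- c("x", "y")
    m
  })
  names(polys) <- tab$ea_id
  ea_set(tab, polygons = polys)
}

#' Write a flow ledger as JSON
#' @param ledger a [flow_ledger()].
#' @param file output path.
#' @export
write_ledger_json <- function(ledger, file) {
  jsonlite::write_json(unclass(ledger), file, auto_unbox = TRUE)
  invisible(file)
}

#' Write generative truth as JSON
#' @param truth a [synthetic_truth()].
#' @param file output path.
#' @export
write_truth_json <- function(truth, file) {
  out <- list(beta0 = truth$beta0, beta_tt = truth$beta_tt,
              beta_cov = as.list(truth$beta_cov),
              matern = unclass(truth$matern), iid_sd = truth$iid_sd)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a multi-layer landscape to a directory
#'
#' Each raster layer goes to its own ASCII grid (`<name>.asc`), and the
#' hospital location to `hospital.json`.
#'
#' @param landscape a [generate_landscape()] result.
#' @param dir output directory (created if needed).
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(landscape$layers))
    write_ascii_grid(landscape$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  jsonlite::write_json(
    list(xy = unname(landscape$hospital$xy), rc = landscape$hospital$rc,
         pixel = landscape$hospital$pixel),
    file.path(dir, "hospital.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
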