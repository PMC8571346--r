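#' Regular latitude-longitude grid field
#'
#' Lightweight container for a raster on a regular, cell-center registered
#' lat/lon grid. All fields produced by one world share a single grid
#' definition; latitudes ascend, longitudes live in \[-180, 180).
#'
#' @param values numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @param lat,lon cell-center coordinate vectors (degrees), equally spaced.
#' @param units physical units of `values` (e.g. `"ug m-3"`).
#' @param name short field name.
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(values, lat, lon, units = "", name = "field") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(lat), ncol(values) == length(lon))
  if (length(lat) > 1 && any(diff(lat) <= 0)) stop("latitudes must ascend")
  if (any(!is.finite(values))) stop("grid_field values must be finite")
  structure(
    list(values = values, lat = as.numeric(lat), lon = as.numeric(lon),
         res = c(lat = if (length(lat) > 1) diff(lat)[1] else NA_real_,
                 lon = if (length(lon) > 1) diff(lon)[1] else NA_real_),
         units = units, name = name),
    class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field '%s'> %d x %d cells, res %.3g x %.3g deg, units '%s'\n",
              x$name, length(x$lat), length(x$lon),
              x$res["lat"], x$res["lon"], x$units))
  cat(sprintf("  lat [%.2f, %.2f], lon [%.2f, %.2f], range [%.4g, %.4g]\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Build a grid definition over a rectangular domain
#'
#' Cell centers are placed at `lo + res/2, lo + 3 res/2, ...`; the domain
#' extent must be an integer number of cells.
#'
#' @param res degrees, length 1 (square cells) or 2 `(lat, lon)`.
#' @param lat_range,lon_range domain edges in degrees.
#' @return list with `lat`, `lon`, `res`.
#' @export
make_grid <- function(res, lat_range = c(-20, 20), lon_range = c(-25, 25)) {
  if (length(res) == 1) res <- c(res, res)
  nlat <- diff(lat_range) / res[1]
  nlon <- diff(lon_range) / res[2]
  if (abs(nlat - round(nlat)) > 1e-9 || abs(nlon - round(nlon)) > 1e-9)
    stop("domain extent must be an integer number of cells")
  list(lat = lat_range[1] + res[1] * (seq_len(round(nlat)) - 0.5),
       lon = lon_range[1] + res[2] * (seq_len(round(nlon)) - 0.5),
       res = c(lat = res[1], lon = res[2]))
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    max(abs(a$lat - b$lat)) < tol && max(abs(a$lon - b$lon)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("grid mismatch between '", a$name, "' and '", b$name, "'")
  invisible(TRUE)
}

#' Map each fine cell to the coarse cell containing its center
#'
#' Requires the coarse cell size to be an integer multiple of the fine one
#' and the two grids to share a domain origin (nested grids).
#'
#' @param coarse,fine grid definitions or `grid_field`s.
#' @return list of integer index vectors `ilat`, `ilon` (length = fine dims).
#' @keywords internal
nesting_index <- function(coarse, fine) {
  rlat <- coarse$res["lat"] / fine$res["lat"]
  rlon <- coarse$res["lon"] / fine$res["lon"]
  if (abs(rlat - round(rlat)) > 1e-9 || abs(rlon - round(rlon)) > 1e-9)
    stop("grids do not nest: coarse resolution is not an integer multiple of fine")
  lat0 <- coarse$lat[1] - coarse$res["lat"] / 2
  lon0 <- coarse$lon[1] - coarse$res["lon"] / 2
  ilat <- floor((fine$lat - lat0) / coarse$res["lat"]) + 1L
  ilon <- floor((fine$lon - lon0) / coarse$res["lon"]) + 1L
  if (any(ilat < 1L | ilat > length(coarse$lat)) ||
      any(ilon < 1L | ilon > length(coarse$lon)))
    stop("grids do not nest: fine domain extends beyond the coarse domain")
  list(ilat = ilat, ilon = ilon)
}

# Scoped RNG: evaluate `code` under a seeded Mersenne-Twister stream and
# restore the caller's RNG state afterwards, so generation is a pure
# function of (config, seed).
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  force(code)
}

# Derive a bounded substream seed for a named pipeline stage.
stage_seed <- function(seed, stage) {
  offsets <- c(economy = 11L, emissions = 23L, grids = 37L, ier = 53L,
               perturb = 71L, monte_carlo = 89L, scenario = 101L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483647L
}
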