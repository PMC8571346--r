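#' Write an MRIO table to CSV
#'
#' One wide CSV: rows indexed "region:sector", transaction columns with the
#' same index, final-demand columns `F:<region>` (destination-resolved),
#' gross output `X`, and the sector `category` tag. All values monetary.
#'
#' @param mrio an `mrio_table`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_mrio_csv <- function(mrio, path) {
  df <- data.frame(index = names(mrio$X),
                   category = mrio$index$category,
                   as.data.frame(mrio$Z, check.names = FALSE),
                   check.names = FALSE)
  fd <- as.data.frame(mrio$F, check.names = FALSE)
  names(fd) <- paste0("F:", colnames(mrio$F))
  df <- cbind(df, fd, X = mrio$X)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an MRIO table written by [write_mrio_csv()]
#'
#' @param path CSV file.
#' @return an `mrio_table` (validated).
#' @export
read_mrio_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- df$index
  parts <- strsplit(lab, ":", fixed = TRUE)
  idx <- data.frame(region = vapply(parts, `[`, "", 1),
                    sector = vapply(parts, `[`, "", 2),
                    category = df$category, stringsAsFactors = FALSE)
  Z <- as.matrix(df[, lab, drop = FALSE])
  fcols <- grep("^F:", names(df), value = TRUE)
  F <- as.matrix(df[, fcols, drop = FALSE])
  colnames(F) <- sub("^F:", "", fcols)
  X <- df$X
  names(X) <- lab
  dimnames(Z) <- list(lab, lab)
  rownames(F) <- lab
  mrio <- structure(list(Z = Z, F = F, X = X, index = idx,
                         regions = colnames(F)), class = "mrio_table")
  validate_mrio(mrio)
  mrio
}

#' Write sectoral emissions to CSV
#'
#' Columns: index ("region:sector"), category, output, emissions (Gg a-1).
#'
#' @param emissions a `sector_emissions` table.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_emissions_csv <- function(emissions, path) {
  df <- data.frame(index = paste(emissions$region, emissions$sector, sep = ":"),
                   category = emissions$category,
                   output = emissions$output,
                   emissions_gg = emissions$emissions)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read sectoral emissions written by [write_emissions_csv()]
#'
#' @param path CSV file.
#' @return a `sector_emissions` table.
#' @export
read_emissions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  parts <- strsplit(df$index, ":", fixed = TRUE)
  out <- data.frame(region = vapply(parts, `[`, "", 1),
                    sector = vapply(parts, `[`, "", 2),
                    category = df$category, output = df$output,
                    emissions = df$emissions_gg, stringsAsFactors = FALSE)
  if (any(out$emissions < 0)) stop("negative emissions in ", path)
  class(out) <- c("sector_emissions", "data.frame")
  out
}

#' Write a grid field as long-format CSV with a JSON metadata sidecar
#'
#' The CSV holds lat, lon, value rows (cell centers); `<path>.meta.json`
#' records name, units and resolution.
#'
#' @param gf a `grid_field`.
#' @param path CSV output file.
#' @return invisibly `path`.
#' @export
write_grid_csv <- function(gf, path) {
  df <- data.frame(lat = rep(gf$lat, times = length(gf$lon)),
                   lon = rep(gf$lon, each = length(gf$lat)),
                   value = as.vector(gf$values))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(name = gf$name, units = gf$units,
               res = as.list(gf$res),
               nlat = length(gf$lat), nlon = length(gf$lon))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grid field written by [write_grid_csv()]
#'
#' @param path CSV file.
#' @return a `grid_field`.
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  vals <- matrix(NA_real_, length(lat), length(lon))
  vals[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$value
  grid_field(vals, lat, lon, units = meta$units, name = meta$name)
}
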