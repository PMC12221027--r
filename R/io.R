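## File formats: NetCDF for every gridded product (ncdf4), CSV for
## tables (data.table), YAML for crop parameters and configuration,
## JSON for reports and run manifests. Round trips are value-exact
## (double precision end to end) and preserve the no-data mask.

MISSVAL <- -1.0e30

nc_geom_atts <- function(nc, geom) {
  ncdf4::ncatt_put(nc, 0, "xll", geom$xll)
  ncdf4::ncatt_put(nc, 0, "yll", geom$yll)
  ncdf4::ncatt_put(nc, 0, "cellsize", geom$cellsize)
  ncdf4::ncatt_put(nc, 0, "crs", geom$crs)
}

nc_read_geom <- function(nc, nrow, ncol) {
  ps_geom(nrow, ncol,
          xll = ncdf4::ncatt_get(nc, 0, "xll")$value,
          yll = ncdf4::ncatt_get(nc, 0, "yll")$value,
          cellsize = ncdf4::ncatt_get(nc, 0, "cellsize")$value,
          crs = ncdf4::ncatt_get(nc, 0, "crs")$value)
}

na_encode <- function(x) { x[is.na(x)] <- MISSVAL; x }
na_decode <- function(x) { x[x == MISSVAL] <- NA_real_; x }

#' Write / read a climate cube as NetCDF
#'
#' Dimensions `year, month, y, x`; variables `temperature` (degC) and
#' `precipitation` (mm/month); grid geometry in global attributes.
#'
#' @param cube `ps_cube`.
#' @param path output file.
#' @return `write_cube_nc`: the path, invisibly. `read_cube_nc`: a
#'   `ps_cube`.
#' @export
#' @rdname cube_nc
write_cube_nc <- function(cube, path) {
  dy <- ncdf4::ncdim_def("year", "year", cube$years)
  dm <- ncdf4::ncdim_def("month", "month", 1:12)
  dr <- ncdf4::ncdim_def("y", "cell", seq_len(cube$geom$nrow))
  dc <- ncdf4::ncdim_def("x", "cell", seq_len(cube$geom$ncol))
  vt <- ncdf4::ncvar_def("temperature", "degC", list(dy, dm, dr, dc),
                         MISSVAL, prec = "double")
  vp <- ncdf4::ncvar_def("precipitation", "mm/month", list(dy, dm, dr, dc),
                         MISSVAL, prec = "double")
  nc <- ncdf4::nc_create(path, list(vt, vp))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vt, na_encode(cube$temperature))
  ncdf4::ncvar_put(nc, vp, na_encode(cube$precipitation))
  nc_geom_atts(nc, cube$geom)
  invisible(path)
}

#' @param path NetCDF file written by [write_cube_nc()].
#' @export
#' @rdname cube_nc
read_cube_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  years <- nc$dim$year$vals
  if (nc$dim$month$len != 12L)
    stop("cube in ", path, " does not hold exactly 12 months")
  tt <- na_decode(ncdf4::ncvar_get(nc, "temperature", collapse_degen = FALSE))
  pp <- na_decode(ncdf4::ncvar_get(nc, "precipitation", collapse_degen = FALSE))
  geom <- nc_read_geom(nc, dim(tt)[3], dim(tt)[4])
  climate_cube(years, tt, pp, geom)
}

#' Write / read a 12-month climatology as NetCDF
#'
#' @param clim `ps_climatology`.
#' @param path file path.
#' @return the path invisibly / a `ps_climatology`.
#' @export
#' @rdname climatology_nc
write_climatology_nc <- function(clim, path) {
  dr <- ncdf4::ncdim_def("y", "cell", seq_len(clim$geom$nrow))
  dc <- ncdf4::ncdim_def("x", "cell", seq_len(clim$geom$ncol))
  dm <- ncdf4::ncdim_def("month", "month", 1:12)
  vt <- ncdf4::ncvar_def("temperature", "degC", list(dr, dc, dm),
                         MISSVAL, prec = "double")
  vp <- ncdf4::ncvar_def("precipitation", "mm/month", list(dr, dc, dm),
                         MISSVAL, prec = "double")
  nc <- ncdf4::nc_create(path, list(vt, vp))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vt, na_encode(clim$temperature))
  ncdf4::ncvar_put(nc, vp, na_encode(clim$precipitation))
  nc_geom_atts(nc, clim$geom)
  ncdf4::ncatt_put(nc, 0, "label", clim$label)
  ncdf4::ncatt_put(nc, 0, "window_start", clim$window[1])
  ncdf4::ncatt_put(nc, 0, "window_end", clim$window[2])
  invisible(path)
}

#' @export
#' @rdname climatology_nc
read_climatology_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  tt <- na_decode(ncdf4::ncvar_get(nc, "temperature", collapse_degen = FALSE))
  pp <- na_decode(ncdf4::ncvar_get(nc, "precipitation", collapse_degen = FALSE))
  geom <- nc_read_geom(nc, dim(tt)[1], dim(tt)[2])
  climatology(tt, pp, geom,
              label = ncdf4::ncatt_get(nc, 0, "label")$value,
              window = c(ncdf4::ncatt_get(nc, 0, "window_start")$value,
                         ncdf4::ncatt_get(nc, 0, "window_end")$value))
}

#' Write / read a named stack of grids as NetCDF
#'
#' Each list element becomes one variable: matrices on dims `(y, x)`,
#' row-col-12 arrays on `(y, x, month)`. Used for terrain, soil,
#' suitability and variability products.
#'
#' @param grids named list of matrices / 3-D arrays on one geometry.
#' @param geom `ps_geom`.
#' @param path file path.
#' @return the path invisibly / a named list with attribute `geom`.
#' @export
#' @rdname grids_nc
write_grids_nc <- function(grids, geom, path) {
  dr <- ncdf4::ncdim_def("y", "cell", seq_len(geom$nrow))
  dc <- ncdf4::ncdim_def("x", "cell", seq_len(geom$ncol))
  dm <- ncdf4::ncdim_def("month", "month", 1:12)
  vars <- lapply(names(grids), function(nm) {
    dims <- if (length(dim(grids[[nm]])) == 3L) list(dr, dc, dm)
    else list(dr, dc)
    ncdf4::ncvar_def(nm, "", dims, MISSVAL, prec = "double")
  })
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(grids))
    ncdf4::ncvar_put(nc, vars[[k]], na_encode(grids[[k]] * 1.0))
  nc_geom_atts(nc, geom)
  invisible(path)
}

#' @export
#' @rdname grids_nc
read_grids_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  nms <- names(nc$var)
  out <- lapply(nms, function(nm)
    na_decode(ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)))
  names(out) <- nms
  d <- dim(out[[1]])
  attr(out, "geom") <- nc_read_geom(nc, d[1], d[2])
  out
}

#' Write / read crop parameter sets as YAML
#'
#' One document per crop, mirroring a tolerance table layout: name,
#' duration, per-parameter `amin/omin/omax/amax`, the texture table and
#' the optional kill temperature. Real tolerance tables can be supplied
#' verbatim in this format.
#'
#' @param crops list of `ps_crop`.
#' @param path file path.
#' @return the path invisibly / a list of `ps_crop`.
#' @export
#' @rdname crops_yaml
write_crops_yaml <- function(crops, path) {
  as_list <- function(cr) {
    tz <- function(t) list(amin = t$amin, omin = t$omin,
                           omax = t$omax, amax = t$amax)
    list(name = cr$name, duration_months = cr$duration_months,
         temperature = tz(cr$temperature),
         precipitation = tz(cr$precipitation),
         slope = tz(cr$slope), twi = tz(cr$twi), wind = tz(cr$wind),
         solar = tz(cr$solar), ph = tz(cr$ph),
         texture = as.list(cr$texture),
         kill_temperature = if (is.na(cr$kill_temperature)) NULL
         else cr$kill_temperature)
  }
  yaml::write_yaml(lapply(crops, as_list), path, precision = 17L)
  invisible(path)
}

#' @export
#' @rdname crops_yaml
read_crops_yaml <- function(path) {
  lapply(yaml::read_yaml(path), function(x) {
    tz <- function(l) trapezoid(l$amin, l$omin, l$omax, l$amax)
    crop_params(x$name, x$duration_months,
                temperature = tz(x$temperature),
                precipitation = tz(x$precipitation),
                slope = tz(x$slope), twi = tz(x$twi), wind = tz(x$wind),
                solar = tz(x$solar), ph = tz(x$ph),
                texture = unlist(x$texture),
                kill_temperature = x$kill_temperature %||% NA_real_)
  })
}

#' Write / read proxy records as CSV
#'
#' Long format: `site_id, row, col, year, temperature, precipitation`.
#'
#' @param records `ps_proxy_records`.
#' @param path file path.
#' @return the path invisibly / a `ps_proxy_records`.
#' @export
#' @rdname proxy_csv
write_proxy_csv <- function(records, path) {
  rows <- lapply(records, function(r)
    data.frame(site_id = r$site_id, row = r$row, col = r$col, r$samples))
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}

#' @export
#' @rdname proxy_csv
read_proxy_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  recs <- lapply(split(df, df$site_id), function(s) {
    s <- s[order(s$year), ]
    list(site_id = s$site_id[1], row = s$row[1], col = s$col[1],
         samples = data.frame(year = s$year, temperature = s$temperature,
                              precipitation = s$precipitation))
  })
  structure(unname(recs), class = "ps_proxy_records")
}
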