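#' Growth-model parameter set
#'
#' Bundles the coefficients of the vascular tumour growth model: a
#' Gompertzian tumour compartment with a dynamic carrying capacity driven by
#' endogenous angiogenic stimulation and inhibition, shifted by the avascular
#' floor volume `v_star` below which the model does not apply.
#'
#' The defaults are the reference mouse parameter set used throughout the
#' package's worked examples.  `lambda2` (natural endothelial loss) is kept as
#' a field for completeness but defaults to 0, the convention under which all
#' reference numerics are derived.
#'
#' @param lambda1 Gompertzian growth rate constant (day^-1).
#' @param lambda2 Natural endothelial loss rate (day^-1); default 0.
#' @param c Endogenous stimulation coefficient (mg/(day mm^(3p) kg)).
#'   Must be strictly positive: non-positive values would describe a
#'   self-regressing carrying capacity for an untreated tumour.
#' @param d Endogenous inhibition coefficient (day^-1 mm^-2).
#' @param alpha Stimulator clearance parameter (mg/(mm^(3p) kg)); must be
#'   strictly positive.
#' @param beta Vasculature-abnormality parameter (mm^(3p)).
#' @param p Vasculature-abnormality exponent (dimensionless).
#' @param v_star Avascular threshold volume (mm^3).  Defaults to the volume
#'   of a sphere of diameter 1 mm, `sphere_volume(1)` = 0.5235988 mm^3
#'   (printed as 0.52 at display precision).
#'
#' @return An object of class `growth_params` (a named list of the eight
#'   coefficients).
#' @seealso [rhs_treated()], [steady_state_volume()], [read_growth_params()]
#' @examples
#' gp <- growth_params()
#' steady_state_volume(gp)
#' @export
growth_params <- function(lambda1 = 0.192, lambda2 = 0, c = 5.85,
                          d = 0.00873, alpha = 1, beta = 1, p = 0,
                          v_star = sphere_volume(1)) {
  gp <- list(lambda1 = lambda1, lambda2 = lambda2, c = c, d = d,
             alpha = alpha, beta = beta, p = p, v_star = v_star)
  validate_growth_params(gp)
}

validate_growth_params <- function(gp) {
  fields <- c("lambda1", "lambda2", "c", "d", "alpha", "beta", "p", "v_star")
  missing <- setdiff(fields, names(gp))
  if (length(missing) > 0L) {
    stop("growth_params is missing field(s): ", paste(missing, collapse = ", "))
  }
  for (f in fields) {
    x <- gp[[f]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("growth_params field '", f, "' must be a single finite number")
    }
  }
  if (gp$c <= 0) {
    stop("'c' must be strictly positive (c <= 0 would give a ",
         "self-regressing carrying capacity for an untreated tumour)")
  }
  if (gp$alpha <= 0) stop("'alpha' must be strictly positive")
  for (f in c("lambda1", "lambda2", "d", "beta", "p", "v_star")) {
    if (gp[[f]] < 0) stop("'", f, "' must be non-negative")
  }
  structure(gp[fields], class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Vascular tumour growth parameters:\n")
  vals <- unlist(x)
  print(signif(vals, 6))
  invisible(x)
}

#' Read and write growth parameters
#'
#' A parameter record is a flat table with keys `lambda1`, `lambda2`, `c`,
#' `d`, `alpha`, `beta`, `p`, `v_star`.  Both a one-row wide CSV (one column
#' per key) and a two-column long CSV (`name,value`) are accepted, as is a
#' flat JSON object.  Keys absent from the file keep their [growth_params()]
#' defaults.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return For `read_growth_params`, a `growth_params` object.
#' @export
read_growth_params <- function(path) {
  vals <- read_flat_record(path)
  known <- intersect(names(vals),
                     c("lambda1", "lambda2", "c", "d", "alpha", "beta", "p",
                       "v_star"))
  if (length(known) == 0L) {
    stop("no growth-parameter keys found in '", path, "'")
  }
  do.call(growth_params, as.list(vals[known]))
}

#' @rdname read_growth_params
#' @param params A `growth_params` object to serialize.
#' @export
write_growth_params <- function(params, path) {
  stopifnot(inherits(params, "growth_params"))
  write_flat_record(unclass(params), path)
  invisible(path)
}

## Flat key-value record I/O shared by parameter and regimen readers.
read_flat_record <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.list(rec)) stop("expected a JSON object in '", path, "'")
    return(rec)
  }
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (ncol(df) == 2L && all(tolower(names(df)) %in% c("name", "value"))) {
      names(df) <- tolower(names(df))
      vals <- as.list(df$value)
      names(vals) <- df$name
      return(vals)
    }
    if (nrow(df) != 1L) {
      stop("wide-format CSV '", path, "' must contain exactly one row")
    }
    return(as.list(df[1L, , drop = FALSE]))
  }
  stop("unsupported parameter file extension: '", ext, "'")
}

write_flat_record <- function(rec, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  } else {
    stop("unsupported parameter file extension: '", ext, "'")
  }
  invisible(path)
}

#' Spherical geometry helpers
#'
#' The model treats the tumour as a sphere, so volumes and linear sizes are
#' interconvertible: `sphere_volume(1)` = pi/6 = 0.5236 mm^3 is the avascular
#' limit volume for a 1 mm diameter tumour, and a 200 mm^3 tumour has radius
#' `radius_from_volume(200)` = 3.63 mm.
#'
#' @param diameter Sphere diameter (mm), non-negative.
#' @return `sphere_volume`: volume (mm^3); `radius_from_volume`: radius (mm).
#' @examples
#' sphere_volume(1)
#' radius_from_volume(200)
#' @export
sphere_volume <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter < 0)) {
    stop("'diameter' must be non-negative and finite")
  }
  (pi / 6) * diameter^3
}

#' @rdname sphere_volume
#' @param V Tumour volume (mm^3), non-negative.
#' @export
radius_from_volume <- function(V) {
  if (any(!is.finite(V)) || any(V < 0)) {
    stop("'V' must be non-negative and finite")
  }
  (3 * V / (4 * pi))^(1 / 3)
}
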