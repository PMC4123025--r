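#' Define a city sampling domain
#'
#' A city layout describes the rectangular projected-coordinate domain over
#' which monitoring sites are placed, the number of sites, and the urban core
#' (the sub-rectangle that receives the dense 250 m prediction grid). All
#' coordinates are in projected meters. Every campaign has exactly two
#' sampling windows, labelled `"winter"` and `"summer"`.
#'
#' @param city_id Character label for the city.
#' @param n_sites Number of monitoring sites (>= 10).
#' @param domain Numeric vector `c(xmin, xmax, ymin, ymax)` in meters.
#' @param urban_core Numeric vector `c(xmin, xmax, ymin, ymax)` contained in
#'   `domain`; defaults to the central third of the domain.
#'
#' @return An object of class `city_layout`.
#' @export
#' @examples
#' city_layout("chicago", n_sites = 40)
city_layout <- function(city_id,
                        n_sites = 40,
                        domain = c(0, 30000, 0, 30000),
                        urban_core = NULL) {
  stopifnot(is.character(city_id), length(city_id) == 1)
  if (n_sites < 10) {
    abort("`n_sites` must be at least 10 for a snapshot campaign.")
  }
  if (length(domain) != 4 || domain[1] >= domain[2] || domain[3] >= domain[4]) {
    abort("`domain` must be c(xmin, xmax, ymin, ymax) with positive extent.")
  }
  if (is.null(urban_core)) {
    dx <- domain[2] - domain[1]
    dy <- domain[4] - domain[3]
    urban_core <- c(
      domain[1] + dx / 3, domain[2] - dx / 3,
      domain[3] + dy / 3, domain[4] - dy / 3
    )
  }
  if (urban_core[1] < domain[1] || urban_core[2] > domain[2] ||
      urban_core[3] < domain[3] || urban_core[4] > domain[4]) {
    abort("`urban_core` must be contained in `domain`.")
  }
  structure(
    list(
      city_id = city_id,
      n_sites = as.integer(n_sites),
      domain = domain,
      urban_core = urban_core,
      seasons = .SEASONS
    ),
    class = "city_layout"
  )
}

#' Default three-city layouts
#'
#' Three cities of roughly 40 sites each over 30 x 30 km domains, mirroring a
#' snapshot campaign run outside the homes of about 40 participants per city.
#'
#' @param n_sites Sites per city.
#' @return A named list of [city_layout()] objects.
#' @export
default_city_layouts <- function(n_sites = 40) {
  list(
    chicago = city_layout("chicago", n_sites = n_sites),
    st_paul = city_layout("st_paul", n_sites = n_sites),
    winston_salem = city_layout("winston_salem", n_sites = n_sites)
  )
}

#' @export
print.city_layout <- function(x, ...) {
  cat(sprintf(
    "<city_layout> %s: %d sites over [%g, %g] x [%g, %g] m\n",
    x$city_id, x$n_sites, x$domain[1], x$domain[2], x$domain[3], x$domain[4]
  ))
  invisible(x)
}
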