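#' Strand-displacement replication model
#'
#' Describes asymmetric replication of a circular genome: leading-strand
#' synthesis starts at the heavy-strand origin `origin_h` and proceeds in
#' one direction around the circle, displacing the parental heavy strand
#' into a single-stranded state; when the fork passes the light-strand
#' origin `origin_l`, lagging synthesis starts there and proceeds in the
#' opposite direction, returning sites to the double-stranded state as it
#' passes. The time a site spends single-stranded (D_ssH) is a known
#' mutation-rate covariate in mitochondrial genomes.
#'
#' @param genome_length circular genome size L in bp.
#' @param origin_h,origin_l 0-based origin positions (distinct).
#' @param direction `+1` (leading fork moves towards increasing coordinates)
#'   or `-1`.
#' @param speed_ratio lagging-fork speed relative to the leading fork
#'   (both forks move one bp per unit time when 1, the default).
#' @param control_region optional length-2 vector `c(start, end)` (0-based
#'   half-open) of sites omitted from D_ssH analyses (the regulatory
#'   control region containing `origin_h`).
#' @return an object of class `replication_model`.
#' @export
replication_model <- function(genome_length, origin_h, origin_l,
                              direction = 1L, speed_ratio = 1,
                              control_region = NULL) {
  L <- as.integer(genome_length)
  origin_h <- as.integer(origin_h); origin_l <- as.integer(origin_l)
  if (origin_h == origin_l) stop("origins must be distinct")
  if (any(c(origin_h, origin_l) < 0L) || any(c(origin_h, origin_l) >= L))
    stop("origins must lie in 0..L-1")
  if (!direction %in% c(1L, -1L)) stop("direction must be +1 or -1")
  if (speed_ratio <= 0) stop("speed_ratio must be positive")
  if (!is.null(control_region)) {
    control_region <- as.integer(control_region)
    if (length(control_region) != 2L || control_region[1] >= control_region[2])
      stop("control_region must be c(start, end) with start < end")
  }
  structure(list(genome_length = L, origin_h = origin_h, origin_l = origin_l,
                 direction = as.integer(direction), speed_ratio = speed_ratio,
                 control_region = control_region),
            class = "replication_model")
}

in_control <- function(model, sites) {
  cr <- model$control_region
  if (is.null(cr)) rep(FALSE, length(sites)) else (sites >= cr[1] & sites < cr[2])
}

#' Duration of single-strandedness (D_ssH) at genome sites
#'
#' Closed form under the strand-displacement model with fork speeds
#' leading = 1, lagging = `speed_ratio` bp per unit time. Writing `d` for
#' the leading-strand distance of the site from the heavy-strand origin and
#' `D` for the leading distance from the heavy-strand to the light-strand
#' origin: on the major arc (`d <= D`) the site is single-stranded from
#' fork arrival at time `d` until the lagging fork, launched at time `D`,
#' reaches it, giving `D_ssH = (1 + 1/r)(D - d)`; on the minor arc
#' (`d = D + y`) the lagging fork approaches from the other side over a
#' distance `L - y`, giving `D_ssH = max((L - y)/r - y, 0)`. With unit speed ratio
#' these reduce to `2(D - d)` and `max(L - 2y, 0)`.
#'
#' @param model a [replication_model].
#' @param sites 0-based positions (default: every site in the genome).
#' @param minor_arc `"wrap"` (default) applies the wrap-around expression
#'   on the minor arc; `"exclude"` returns `NA` there.
#' @return numeric vector of durations (bp-time units). Requesting a site
#'   inside the model's control region is an error; use [dssh_track()] for
#'   a genome-wide vector with the control region masked.
#' @export
compute_dssh <- function(model, sites = seq_len(model$genome_length) - 1L,
                         minor_arc = c("wrap", "exclude")) {
  stopifnot(inherits(model, "replication_model"))
  minor_arc <- match.arg(minor_arc)
  sites <- as.integer(sites)
  L <- model$genome_length
  if (any(sites < 0L | sites >= L)) stop("sites must lie in 0..L-1")
  if (any(in_control(model, sites)))
    stop("site(s) inside the omitted control region; use dssh_track() for a masked genome-wide track")
  r <- model$speed_ratio
  d <- ((sites - model$origin_h) * model$direction) %% L
  D <- ((model$origin_l - model$origin_h) * model$direction) %% L
  out <- numeric(length(sites))
  major <- d <= D
  out[major] <- (1 + 1 / r) * (D - d[major])
  y <- d[!major] - D
  out[!major] <- pmax((L - y) / r - y, 0)
  if (minor_arc == "exclude") out[!major] <- NA_real_
  out
}

#' Genome-wide D_ssH track with the control region masked
#'
#' @inheritParams compute_dssh
#' @return a [score_track]-style numeric vector of length L with `NA` inside
#'   the control region (and on the minor arc if `minor_arc = "exclude"`).
#' @export
dssh_track <- function(model, minor_arc = c("wrap", "exclude")) {
  minor_arc <- match.arg(minor_arc)
  L <- model$genome_length
  sites <- seq_len(L) - 1L
  mask <- in_control(model, sites)
  out <- rep(NA_real_, L)
  out[!mask] <- compute_dssh(model, sites[!mask], minor_arc)
  out
}
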