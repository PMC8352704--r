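# Airway cross-section quantification: threshold segmentation with
# connected-component topology (lumen = largest dark component fully
# enclosed by bright wall pixels; wall = the enclosing bright component),
# then pixel-counting areas.  LA = lumen area, WA = wall area,
# WA% = 100 * WA / (WA + LA) -- the standard airway-CT convention.
# Validated against the analytic annulus phantoms from generate_phantom().

# 4-connected component labeling of a logical matrix via BFS with an
# integer frontier; images here are small (<= a few hundred px per side).
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- integer(h * w)
  m <- as.vector(mask)
  nxt <- 0L
  for (start in which(m & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[start] <- nxt
    while (length(frontier)) {
      i <- ((frontier - 1L) %% h) + 1L
      j <- ((frontier - 1L) %/% h) + 1L
      nb <- c(frontier[i > 1L] - 1L, frontier[i < h] + 1L,
              frontier[j > 1L] - h, frontier[j < w] + h)
      nb <- unique(nb[m[nb] & lab[nb] == 0L])
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  matrix(lab, h, w)
}

# linear indices of 4-neighbors outside the component
component_boundary <- function(comp) {
  h <- nrow(comp); w <- ncol(comp)
  idx <- which(comp)
  i <- ((idx - 1L) %% h) + 1L
  j <- ((idx - 1L) %/% h) + 1L
  nb <- c(idx[i > 1L] - 1L, idx[i < h] + 1L, idx[j > 1L] - h, idx[j < w] + h)
  setdiff(unique(nb), idx)
}

touches_border <- function(comp) {
  any(comp[1L, ]) || any(comp[nrow(comp), ]) ||
    any(comp[, 1L]) || any(comp[, ncol(comp)])
}

#' Segment an airway cross-section into lumen and wall masks
#'
#' The lumen is the largest connected below-`lumen_threshold` component that
#' does not touch the image border and whose entire 4-neighborhood boundary
#' lies above `wall_threshold` (i.e. is fully enclosed by wall); the wall is
#' the above-`wall_threshold` connected component enclosing it.  The two
#' masks are disjoint by construction.
#'
#' @param image 2-D numeric intensity matrix (lumen dark, wall bright).
#' @param lumen_threshold intensities strictly below this are lumen
#'   candidates.
#' @param wall_threshold intensities strictly above this are wall.
#' @return list with logical matrices `lumen` and `wall`.
#' @export
segment_airway <- function(image, lumen_threshold = 0.25,
                           wall_threshold = 0.6) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (lumen_threshold >= wall_threshold)
    stop("thresholds must satisfy lumen_threshold < wall_threshold")
  wall_px <- image > wall_threshold
  labs <- label_components(image < lumen_threshold)
  n_comp <- max(labs)
  if (n_comp > 0L) {
    sizes <- tabulate(labs[labs > 0L], n_comp)
    for (lb in order(sizes, decreasing = TRUE)) {
      comp <- labs == lb
      if (touches_border(comp)) next
      bnd <- component_boundary(comp)
      if (length(bnd) && all(wall_px[bnd])) {
        wall_labs <- label_components(wall_px)
        wall <- wall_labs == wall_labs[bnd[1L]]
        return(list(lumen = comp, wall = wall & !comp))
      }
    }
  }
  stop("no enclosed lumen found: not an airway cross-section")
}

#' Measure lumen and wall areas from segmentation masks
#'
#' Areas are pixel counts scaled by `pixel_size^2`; equivalent diameters
#' treat areas as circles (`d = 2 * sqrt(A / pi)`), and the equivalent wall
#' thickness is the difference of equivalent outer and lumen radii.
#'
#' @param masks a [segment_airway()] result (logical `lumen` / `wall`).
#' @param pixel_size mm per pixel (> 0).
#' @return An object of class `airway_measurement`: list `LA`, `WA`
#'   (mm^2), `WA_percent`, `lumen_diameter_equivalent`,
#'   `wall_thickness_equivalent` (mm).
#' @export
measure_airway <- function(masks, pixel_size = 1) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  n_lumen <- sum(masks$lumen)
  if (n_lumen == 0L) stop("empty lumen mask")
  la <- n_lumen * pixel_size^2
  wa <- sum(masks$wall) * pixel_size^2
  r_lumen <- sqrt(la / pi)
  r_outer <- sqrt((la + wa) / pi)
  structure(list(LA = la, WA = wa,
                 WA_percent = 100 * wa / (wa + la),
                 lumen_diameter_equivalent = 2 * r_lumen,
                 wall_thickness_equivalent = r_outer - r_lumen),
            class = "airway_measurement")
}

#' Descriptive group summaries of airway measurements
#'
#' Mean and standard deviation of each quantity per (group, level); a group
#' level with a single measurement reports `NA` for the sd.
#'
#' @param measurements data.frame with columns `group`, `level` (opaque
#'   bronchial-generation tag), `LA`, `WA`, `WA_percent`.
#' @return data.frame: group, level, n, and mean/sd columns for LA, WA and
#'   WA_percent.
#' @export
compare_groups <- function(measurements) {
  req <- c("group", "level", "LA", "WA", "WA_percent")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns ", paste(req, collapse = ", "))
  if (nrow(measurements) == 0L) stop("no measurements")
  key <- interaction(measurements$group, measurements$level, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    d <- measurements[key == k, ]
    data.frame(group = d$group[1L], level = d$level[1L], n = nrow(d),
               LA_mean = mean(d$LA), LA_sd = if (nrow(d) > 1L) stats::sd(d$LA) else NA_real_,
               WA_mean = mean(d$WA), WA_sd = if (nrow(d) > 1L) stats::sd(d$WA) else NA_real_,
               WA_percent_mean = mean(d$WA_percent),
               WA_percent_sd = if (nrow(d) > 1L) stats::sd(d$WA_percent) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$group, out$level), , drop = FALSE]
}
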