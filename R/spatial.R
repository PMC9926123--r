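#' Detector grid of the visible burrow system
#'
#' The VBS floor is instrumented with a grid of 32 RFID detectors (4 rows by
#' 8 columns here, arbitrary coordinate units). Columns 1-4 lie under the
#' open area (with the feeder and water zones in its first column), column 5
#' under the connecting tunnels, and columns 6-8 under the covered burrow
#' (chambers and tunnels). Adjacency is rook adjacency on the grid.
#'
#' @param nrow,ncol grid dimensions (defaults 4 x 8 = 32 detectors).
#' @return list of class `zone_grid` with elements `zones` (data.frame:
#'   `detector`, `x`, `y`, `label`), `k` (number of detectors) and
#'   `adjacency` (k x k binary matrix).
#' @export
#' @examples
#' g <- zone_grid()
#' table(g$zones$label)
zone_grid <- function(nrow = 4, ncol = 8) {
  if (nrow * ncol < 2) stop("a grid needs at least 2 detectors")
  zones <- expand.grid(y = seq_len(nrow), x = seq_len(ncol))
  zones <- data.frame(detector = seq_len(nrow * ncol),
                      x = zones$x, y = zones$y)
  lab <- rep("open_area", nrow(zones))
  lab[zones$x == ceiling(ncol * 5 / 8)] <- "tunnel"
  lab[zones$x > ceiling(ncol * 5 / 8)] <- "burrow"
  feeder <- which(zones$x == 1 & zones$y == 1)[1]
  water <- which(zones$x == 1 & zones$y == nrow)[1]
  lab[feeder] <- "feeder"
  lab[water] <- "water"
  zones$label <- lab
  k <- nrow(zones)
  adj <- matrix(0L, k, k)
  d <- abs(outer(zones$x, zones$x, "-")) + abs(outer(zones$y, zones$y, "-"))
  adj[d == 1] <- 1L
  if (any(rowSums(adj) == 0))
    stop("invalid grid: detector(s) without adjacency")
  structure(list(zones = zones, k = k, adjacency = adj), class = "zone_grid")
}

#' Labels counted as the open area
#' @keywords internal
open_labels <- c("open_area", "feeder", "water")

#' Expand dwell intervals into 1-second detections
#'
#' RFID streams are event-based: an animal occupies its last-seen detector
#' until the next detection. Each dwell interval is expanded into one
#' detection per second at its detector so that longer stays weigh more in
#' the occupancy frequencies.
#'
#' @param stream data.frame with columns `animal`, `day`, `phase`, `time`
#'   (s from phase start), `detector`, `duration` (s).
#' @param resolution slice length in seconds (default 1).
#' @return data.frame `animal`, `day`, `phase`, `time`, `detector`, one row
#'   per slice.
#' @export
slice_detections <- function(stream, resolution = 1) {
  if (!"duration" %in% names(stream))  # already sliced
    return(stream[, c("animal", "day", "phase", "time", "detector")])
  if (nrow(stream) == 0)
    return(data.frame(animal = character(0), day = integer(0),
                      phase = character(0), time = numeric(0),
                      detector = integer(0)))
  o <- order(stream$animal, stream$day, stream$phase, stream$time)
  s <- stream[o, , drop = FALSE]
  same <- c(FALSE, s$animal[-1] == s$animal[-nrow(s)] &
                   s$day[-1] == s$day[-nrow(s)] &
                   s$phase[-1] == s$phase[-nrow(s)])
  overlap <- same & s$time < c(-Inf, s$time + s$duration)[seq_len(nrow(s))]
  if (any(overlap))
    stop("overlapping dwell intervals for a single animal")
  n <- pmax(0L, as.integer(floor(s$duration / resolution)))
  idx <- rep(seq_len(nrow(s)), n)
  off <- (sequence(n) - 1) * resolution
  data.frame(animal = s$animal[idx], day = s$day[idx], phase = s$phase[idx],
             time = s$time[idx] + off, detector = s$detector[idx])
}

#' Per-detector occupancy frequencies
#'
#' Observed detection probabilities p (one per detector) for an animal
#' within a day/phase window, computed from 1-second slices.
#'
#' @param sliced output of [slice_detections()] (or a stream, which will be
#'   sliced).
#' @param k number of detectors.
#' @param days,phases window restriction.
#' @return matrix animals x detectors of frequencies; rows sum to 1 for
#'   animals with any detections (all-zero otherwise).
#' @export
occupancy_profile <- function(sliced, k, days = 1:4, phases = "dark") {
  if ("duration" %in% names(sliced)) sliced <- slice_detections(sliced)
  s <- sliced[sliced$day %in% days & sliced$phase %in% phases, , drop = FALSE]
  animals <- sort(unique(sliced$animal))
  tab <- table(factor(s$animal, levels = animals),
               factor(s$detector, levels = seq_len(k)))
  m <- matrix(as.numeric(tab), nrow = length(animals),
              dimnames = list(animals, seq_len(k)))
  tot <- rowSums(m)
  m[tot > 0, ] <- m[tot > 0, , drop = FALSE] / tot[tot > 0]
  m
}

#' Roaming entropy
#'
#' Normalized Shannon entropy of an animal's detection frequencies across
#' the k detectors: RE = -sum(p log p) / log(k), with 0 log 0 = 0. RE is 0
#' when the animal is always at one detector and 1 when detections are
#' uniform over the grid. Natural logarithms are used in both numerator and
#' denominator (the ratio is base-invariant).
#'
#' @param p vector of detection frequencies (must sum to 1, or be all zero
#'   for an animal never detected, which yields NA).
#' @param k number of detectors (>= 2); defaults to `length(p)`.
#' @return RE in `[0, 1]` (NA if no detections).
#' @export
#' @examples
#' roaming_entropy(rep(1 / 32, 32))          # 1
#' roaming_entropy(c(1, rep(0, 31)))         # 0
#' roaming_entropy(c(.5, .5, rep(0, 30)))    # log(2)/log(32) = 0.2
roaming_entropy <- function(p, k = length(p)) {
  if (k < 2) stop("roaming entropy requires k >= 2 detectors")
  if (all(p == 0)) return(NA_real_)
  if (abs(sum(p) - 1) > 1e-8) stop("frequencies must sum to 1")
  nz <- p[p > 0]
  -sum(nz * log(nz)) / log(k)
}

#' Daily and total roaming entropy from a detection stream
#'
#' Daily RE is computed per (animal, day) from the dark-phase occupancy
#' frequencies of that day; total RE from detections pooled over the dark
#' phases of the first four days (pooled detections, not the mean of daily
#' values).
#'
#' @param stream detection stream (dwell intervals).
#' @param grid a [zone_grid()].
#' @param days days to analyze (default 1:4).
#' @param phases phases used (default `"dark"`).
#' @return list with `daily` (data.frame `animal`, `day`, `re`) and `total`
#'   (named vector per animal).
#' @export
roaming_entropy_stream <- function(stream, grid = zone_grid(), days = 1:4,
                                   phases = "dark") {
  sliced <- slice_detections(stream)
  daily <- do.call(rbind, lapply(days, function(d) {
    m <- occupancy_profile(sliced, grid$k, days = d, phases = phases)
    data.frame(animal = rownames(m), day = d,
               re = apply(m, 1, roaming_entropy, k = grid$k))
  }))
  rownames(daily) <- NULL
  m <- occupancy_profile(sliced, grid$k, days = days, phases = phases)
  total <- apply(m, 1, roaming_entropy, k = grid$k)
  list(daily = daily, total = total)
}

#' Distance-traveled index
#'
#' Sum of Euclidean distances (arbitrary units) between consecutive distinct
#' detector coordinates, binned per hour aligned to phase start. The total
#' per animal is the activity feature "Total distance traveled".
#'
#' @param stream detection stream (dwell intervals).
#' @param grid a [zone_grid()].
#' @param days days included (default 1:4).
#' @return list with `hourly` (data.frame `animal`, `day`, `phase`, `hour`,
#'   `distance`) and `total` (named vector per animal).
#' @export
distance_index <- function(stream, grid = zone_grid(), days = 1:4) {
  s <- stream[stream$day %in% days, , drop = FALSE]
  s <- s[order(s$animal, s$day, s$phase, s$time), , drop = FALSE]
  animals <- sort(unique(stream$animal))
  if (nrow(s) < 2) {
    hourly <- data.frame(animal = character(0), day = integer(0),
                         phase = character(0), hour = integer(0),
                         distance = numeric(0))
    return(list(hourly = hourly,
                total = stats::setNames(numeric(length(animals)), animals)))
  }
  xy <- grid$zones[match(s$detector, grid$zones$detector), c("x", "y")]
  n <- nrow(s)
  same <- s$animal[-1] == s$animal[-n] & s$day[-1] == s$day[-n] &
          s$phase[-1] == s$phase[-n]
  step <- sqrt(diff(xy$x)^2 + diff(xy$y)^2)
  step[!same] <- NA
  seg <- data.frame(animal = s$animal[-1], day = s$day[-1],
                    phase = s$phase[-1], hour = floor(s$time[-1] / 3600),
                    distance = step)
  seg <- seg[!is.na(seg$distance) & seg$distance > 0, , drop = FALSE]
  hourly <- stats::aggregate(distance ~ animal + day + phase + hour, seg, sum)
  tot <- stats::setNames(numeric(length(animals)), animals)
  if (nrow(seg)) {
    agg <- tapply(seg$distance, factor(seg$animal, levels = animals), sum)
    tot[names(agg)] <- ifelse(is.na(agg), 0, agg)
  }
  list(hourly = hourly, total = tot)
}

#' Place-preference maps and genotype difference map
#'
#' Per-detector percentage of detections per genotype (mean over animals of
#' each animal's own percentage profile) and the difference map between the
#' two genotypes, split by phase.
#'
#' @param stream detection stream for all animals.
#' @param genotype named character vector animal -> genotype (two levels;
#'   the difference is first level minus second, in the order of
#'   `sort(unique(genotype))` unless `genotype` is a factor).
#' @param grid a [zone_grid()].
#' @param days,phases window (default days 1:4, phase `"dark"`).
#' @return list with `percent` (genotype x detector matrix, rows sum to
#'   100) and `difference` (vector summing to 0).
#' @export
place_preference_maps <- function(stream, genotype, grid = zone_grid(),
                                  days = 1:4, phases = "dark") {
  lev <- if (is.factor(genotype)) levels(genotype) else sort(unique(genotype))
  if (length(lev) != 2) stop("exactly two genotypes are required")
  occ <- occupancy_profile(slice_detections(stream), grid$k,
                           days = days, phases = phases)
  g <- as.character(genotype[rownames(occ)])
  pct <- rbind(colMeans(occ[g == lev[1], , drop = FALSE]) * 100,
               colMeans(occ[g == lev[2], , drop = FALSE]) * 100)
  rownames(pct) <- lev
  list(percent = pct, difference = pct[1, ] - pct[2, ])
}

#' Preference for the open area
#'
#' Fraction of an animal's 1-second detection slices falling in open-area
#' zones (open area proper, feeder and water zones).
#'
#' @param stream detection stream.
#' @param grid a [zone_grid()].
#' @param days,phases window (defaults: days 1:4, both phases).
#' @return named vector in `[0, 1]` per animal (NA if no detections).
#' @export
open_area_preference <- function(stream, grid = zone_grid(), days = 1:4,
                                 phases = c("dark", "light")) {
  sliced <- slice_detections(stream)
  s <- sliced[sliced$day %in% days & sliced$phase %in% phases, , drop = FALSE]
  open <- grid$zones$detector[grid$zones$label %in% open_labels]
  animals <- sort(unique(stream$animal))
  tot <- table(factor(s$animal, levels = animals))
  opn <- table(factor(s$animal[s$detector %in% open], levels = animals))
  out <- as.numeric(opn) / as.numeric(tot)
  stats::setNames(out, animals)
}
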