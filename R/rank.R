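#' Glicko rating trajectories from a sequence of interaction outcomes
#'
#' Sequential Glicko updates (rating + rating deviation RD) over an ordered
#' sequence of win/loss outcomes, one rating period per interaction: the
#' initiator of an aggressive or sexual interaction is the winner (score 1)
#' and the receiver the loser (score 0). At each period every animal's RD
#' grows by the deviation constant `cval` (capped at `init_rd`), then the
#' two participants are updated with Glickman's equations
#' (q = ln(10)/400, g(RD) = 1/sqrt(1 + 3 q^2 RD^2 / pi^2),
#' E = 1/(1 + 10^(-g(RD_opp) (r - r_opp)/400)),
#' d^2 = 1/(q^2 g^2 E (1 - E)),
#' r' = r + q / (1/RD^2 + 1/d^2) * g * (s - E),
#' RD' = sqrt(1 / (1/RD^2 + 1/d^2))).
#'
#' @param outcomes data.frame with columns `winner`, `loser` in time order.
#' @param animals animal ids (defaults to those appearing in `outcomes`);
#'   animals never involved keep their initial values.
#' @param init_rating,init_rd,cval initial rating, initial deviation and
#'   per-period deviation growth (defaults 2200, 300, 15, the convention of
#'   the rating toolkit commonly used for dyadic animal data).
#' @return object of class `glicko_history`: list with `ratings` and
#'   `deviations` ((n_outcomes + 1) x n_animals matrices, row 1 = initial
#'   state), `animals`, `outcomes` and the parameters.
#' @export
glicko_trajectory <- function(outcomes, animals = NULL,
                              init_rating = 2200, init_rd = 300, cval = 15) {
  if (is.null(animals))
    animals <- sort(unique(c(outcomes$winner, outcomes$loser)))
  if (nrow(outcomes) > 0 && any(outcomes$winner == outcomes$loser))
    stop("winner and loser must differ")
  q <- log(10) / 400
  n <- length(animals)
  m <- nrow(outcomes)
  r <- stats::setNames(rep(init_rating, n), animals)
  rd <- stats::setNames(rep(init_rd, n), animals)
  R <- matrix(NA_real_, m + 1, n, dimnames = list(NULL, animals))
  D <- R
  R[1, ] <- r; D[1, ] <- rd
  g_fun <- function(rd) 1 / sqrt(1 + 3 * q^2 * rd^2 / pi^2)
  if (m > 0) for (i in seq_len(m)) {
    rd <- pmin(sqrt(rd^2 + cval^2), init_rd)
    w <- as.character(outcomes$winner[i]); l <- as.character(outcomes$loser[i])
    upd <- function(ri, rdi, rj, rdj, s) {
      g <- g_fun(rdj)
      e <- 1 / (1 + 10^(-g * (ri - rj) / 400))
      d2 <- 1 / (q^2 * g^2 * e * (1 - e))
      denom <- 1 / rdi^2 + 1 / d2
      c(ri + q / denom * g * (s - e), sqrt(1 / denom))
    }
    new_w <- upd(r[w], rd[w], r[l], rd[l], 1)
    new_l <- upd(r[l], rd[l], r[w], rd[w], 0)
    r[w] <- new_w[1]; rd[w] <- new_w[2]
    r[l] <- new_l[1]; rd[l] <- new_l[2]
    R[i + 1, ] <- r; D[i + 1, ] <- rd
  }
  structure(list(ratings = R, deviations = D, animals = animals,
                 outcomes = outcomes, init_rating = init_rating,
                 init_rd = init_rd, cval = cval),
            class = "glicko_history")
}

#' @export
print.glicko_history <- function(x, ...) {
  cat("Glicko rating history:", length(x$animals), "animals,",
      nrow(x$outcomes), "interactions\n")
  fin <- sort(x$ratings[nrow(x$ratings), ], decreasing = TRUE)
  cat("final ratings:\n")
  print(round(fin, 1))
  invisible(x)
}

#' Final Glicko ratings
#' @param history a `glicko_history`.
#' @return named vector of final ratings.
#' @export
final_ratings <- function(history) {
  history$ratings[nrow(history$ratings), ]
}

#' Online Bayesian change-point detection on a rating trajectory
#'
#' Run-length filtering with a constant hazard and a Gaussian observation
#' model with conjugate (normal-inverse-gamma) unknown mean and variance,
#' giving a Student-t predictive. A change point is an index where the MAP
#' run length resets. The observation noise scale is initialized from the
#' median absolute deviation of the first differences (floored to keep the
#' prior proper on constant input).
#'
#' @param x numeric trajectory (length >= 2).
#' @param hazard constant hazard in (0, 1) (default 1/50).
#' @param kappa0,alpha0 prior strength parameters of the
#'   normal-inverse-gamma prior.
#' @param n_interactions optional group total number of interactions; if
#'   given, the normalized change-point count (count divided by this total)
#'   is included.
#' @return list with `change_points` (indices where a new regime starts),
#'   `n` (count), `map_run_length`, and `normalized` when
#'   `n_interactions` is supplied.
#' @export
detect_change_points <- function(x, hazard = 1 / 50, kappa0 = 1, alpha0 = 1,
                                 n_interactions = NULL) {
  if (length(x) < 2) stop("trajectory must have length >= 2")
  if (hazard <= 0 || hazard >= 1) stop("hazard must be in (0, 1)")
  t_max <- length(x)
  sigma0 <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma0) || sigma0 < 1e-6) sigma0 <- 1e-6
  beta0 <- sigma0^2
  mu0 <- x[1]
  # aligned state vectors, one entry per run-length hypothesis
  rl <- 0L; logp <- 0
  mu <- mu0; kap <- kappa0; alp <- alpha0; bet <- beta0
  map_rl <- integer(t_max)
  logsumexp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  for (t in seq_len(t_max)) {
    scale2 <- bet * (kap + 1) / (alp * kap)
    pred <- stats::dt((x[t] - mu) / sqrt(scale2), df = 2 * alp, log = TRUE) -
      0.5 * log(scale2)
    joint <- logp + pred
    logp <- c(logsumexp(joint) + log(hazard), joint + log(1 - hazard))
    rl <- c(0L, rl + 1L)
    bet_upd <- bet + kap * (x[t] - mu)^2 / (2 * (kap + 1))
    mu <- c(mu0, (kap * mu + x[t]) / (kap + 1))
    bet <- c(beta0, bet_upd)
    kap <- c(kappa0, kap + 1)
    alp <- c(alpha0, alp + 0.5)
    logp <- logp - logsumexp(logp)
    keep <- logp > -30
    keep[which.max(logp)] <- TRUE
    keep[1] <- TRUE
    rl <- rl[keep]; logp <- logp[keep]; mu <- mu[keep]
    kap <- kap[keep]; alp <- alp[keep]; bet <- bet[keep]
    map_rl[t] <- rl[which.max(logp)]
  }
  # change point where MAP run length resets (drops instead of growing)
  resets <- which(diff(map_rl) < 0) + 1L
  starts <- unique(resets - map_rl[resets])
  starts <- starts[starts > 1]
  out <- list(change_points = starts, n = length(starts),
              map_run_length = map_rl)
  if (!is.null(n_interactions))
    out$normalized <- length(starts) / n_interactions
  out
}

#' Hierarchy metrics from Glicko trajectories
#'
#' The maximum rating contrast (divergence) of a group is the difference
#' between the highest and lowest final ratings. Dominant animals are those
#' whose final rating exceeds one third of the maximum rating contrast;
#' under the default reading the baseline is the initial rating
#' (final > initial + contrast/3, strict), with the alternative baseline
#' (group minimum) available via `rule = "minimum"`. Change points are
#' detected per animal on its rating trajectory and normalized by the group
#' total number of interactions.
#'
#' @param history a `glicko_history`.
#' @param rule dominance baseline: `"initial"` (default) or `"minimum"`.
#' @param cpd logical: run change-point detection per animal (default TRUE).
#' @param hazard hazard for [detect_change_points()].
#' @return list of class `hierarchy_metrics`: `final_ratings`,
#'   `max_rating_contrast`, `dominants`, `change_points`,
#'   `normalized_change_points`, `n_interactions`.
#' @export
hierarchy_metrics <- function(history, rule = c("initial", "minimum"),
                              cpd = TRUE, hazard = 1 / 50) {
  rule <- match.arg(rule)
  fin <- final_ratings(history)
  contrast <- max(fin) - min(fin)
  base <- if (rule == "initial") history$init_rating else min(fin)
  dominants <- names(fin)[fin > base + contrast / 3]
  n_int <- nrow(history$outcomes)
  cps <- norm_cps <- NULL
  if (cpd && nrow(history$ratings) >= 2) {
    cps <- vapply(history$animals, function(a) {
      detect_change_points(history$ratings[, a], hazard = hazard)$n
    }, numeric(1))
    norm_cps <- if (n_int > 0) cps / n_int else cps * NA
  }
  structure(list(final_ratings = fin, max_rating_contrast = contrast,
                 dominants = dominants, change_points = cps,
                 normalized_change_points = norm_cps,
                 n_interactions = n_int, rule = rule),
            class = "hierarchy_metrics")
}

#' @export
print.hierarchy_metrics <- function(x, ...) {
  cat("Hierarchy metrics (", x$n_interactions, " interactions)\n", sep = "")
  cat("max rating contrast:", round(x$max_rating_contrast, 1), "\n")
  cat("dominant(s):", if (length(x$dominants)) paste(x$dominants, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Blanchard dominance score
#'
#' Within a housed group, time spent in the open area and weight loss are
#' each ranked 1 to `n` (ties receive the mean rank); the Blanchard score
#' is the mean of the two ranks. More open-area time ranks higher; less
#' weight loss ranks higher.
#'
#' @param open_area_time per-animal time in the open area (any monotone
#'   measure, e.g. detection fraction), named vector.
#' @param weight_loss per-animal weight loss (positive = loss), same names.
#' @return named vector of scores in `[1, n]`; group mean is always
#'   (n + 1) / 2.
#' @export
blanchard_score <- function(open_area_time, weight_loss) {
  if (length(open_area_time) != length(weight_loss))
    stop("both measures must cover the same animals")
  r1 <- rank(open_area_time)      # more time in open -> higher rank
  r2 <- rank(-weight_loss)        # less loss -> higher rank
  (r1 + r2) / 2
}
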